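---
title: "Rare-codon identification and synonymous sequence optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-codon identification and synonymous sequence optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonsmith)
```

## The model

A coding sequence is an ordered list of codons read in frame. Against a host
codon usage table — frequencies in permille (‰), occurrences per 1,000
codons across the host's genes — each codon falls into one of three tiers:

| tier | condition | report mark |
|------|-----------|-------------|
| highly rare | f ≤ 5 ‰ | `[[XXX]]` / red |
| rare | 5 ‰ < f < 10 ‰ | `[XXX]` / orange |
| common | f ≥ 10 ‰ | none |

The boundary semantics deserve a word, because the two published statements
of the scheme — rare codons are those "below 10 ‰", and highly rare ones
those "at or below 5 ‰" — constrain both edges. We close the lower boundary
(5 ‰ is still highly rare) and open the upper one (10 ‰ is already common),
which is the only assignment under which both statements hold
simultaneously. `classify_rarity()` implements exactly this partition and
is total and monotone over the frequency axis. Both thresholds are
user-configurable through `rarity_thresholds()` (validated as
0 < highly-rare < rare); the 10 / 5 ‰ defaults are the field's convention
for expression hosts.

Optimization is deliberately single-criterion: a rare codon is replaced by
a synonymous codon with higher (or, when the user chooses, lower) usage
frequency. No multi-objective machinery (GC targets, codon-pair bias, mRNA
secondary structure, motif avoidance) is attempted; the codon-by-codon mode
is the mechanism for any constraint the user wants to impose by hand.

## The three strategies and their guarantees

* `one_click_optimize()` replaces every rare and highly rare codon with its
  synonym family's frequency maximum. Three properties follow from the
  definition and are enforced by tests: the protein is conserved; the
  operation is idempotent; and a position stays rare after optimization
  exactly when its *entire* family is below the rare threshold (cysteine
  and tryptophan in low-GC hosts are typical). We do not hide such
  positions — the report marks them in the output too.
* `bulk_replace()` substitutes every occurrence of one codon with one
  chosen synonym. The rarer direction is intentionally allowed: locally
  slowing translation (mimicking the source organism's rhythm, or avoiding
  clusters of one codon) is a legitimate use.
* `set_codon()` edits a single position. Composing it over all rare
  positions with each family maximum reproduces `one_click_optimize()`
  exactly, which the test-suite checks.

Every strategy validates synonymy under the genetic code in force and
returns a substitution log; replaying the log onto the original reproduces
the optimized sequence, and positions outside the log are untouched.

Two smaller decisions: frequency ties inside a family break
lexicographically on the codon text, so results are deterministic and
documented; and stop codons form an ordinary synonym family (TAA/TAG/TGA
under the standard code) — one-click may swap a rare stop for the host's
preferred stop, which preserves the `*` position of the protein.

## Usage tables and genetic codes

`parse_usage_table()` reads the two plain-text layouts in circulation for
codon usage tables: frequency-only records (`GCG 33.7( 123456)`) and
amino-acid-annotated records (`GCG A 0.36 33.7 ( 123456)`), auto-detected
per record, tolerant of RNA/DNA alphabet, case, whitespace and multiple
records per line. Because users legitimately edit tables (for example to
use the usage of highly expressed genes only), a frequency sum away from
1000 ‰ only clears the `consistent` flag; the parser rejects only
structural defects — missing codons, conflicting duplicates, malformed
records — each with a distinct error class.

Translation follows the standard genetic code by default. When a table in
the annotated dialect is supplied, `code_from_annotated_table()` derives
the code from the table's own amino-acid column, and that code then drives
synonym families and translation — this is how non-standard codes enter,
and the package's resolution of the tension between "standard code" and
"non-standard code support": standard unless the table says otherwise. A
derived code must still map all 64 codons and define at least one stop.

## Restriction scanning

`find_sites()` expands IUPAC ambiguity codes and reports every match,
overlapping ones included. Both strands are scanned — the reverse strand by
matching the reverse-complemented pattern against the input strand, with
coordinates kept on the input strand — and palindromic sites are reported
once. Whether to scan the reverse strand at all was an open design point;
we scan it because that is standard restriction-mapping practice, and a
site is cut regardless of which strand the catalogue happens to write its
recognition sequence on. The bundled catalogue (127 enzymes) was curated by
the package authors from public commercial supplier listings; the
report layer accepts at most two enzymes per run, mirroring the two-enzyme
workflow the interface is designed around, while the library function is
general. Matching itself delegates to Biostrings; the test-suite checks it
against an independent every-offset set-expansion oracle on random
sequences. Coordinates are 0-based half-open internally and rendered
1-based inclusive in reports. Cut positions, overhangs, methylation
sensitivity and star activity are out of scope.

## The fixture generator

`generate_fixture()` draws a seeded random CDS: ATG first, the table's
preferred stop last, and each interior position rare with probability
`rare_fraction` (uniform draws within the rare and common non-stop pools).
It emulates only what the tests need — a sequence with a controllable rare
load under a given table. It does not emulate real genes: no amino-acid
composition bias, no codon autocorrelation, no rare-codon clustering, no
GC gradient. Passing tests therefore demonstrate the *method's algebraic
guarantees* (protein conservation, optimality, round-trips) on arbitrary
sequences, not performance claims about natural genes. A request is
infeasible when the table offers no rare (or no common) non-stop codon to
draw from, and is rejected as such. The generator needs at least two codons
(a start and a stop); the realized rare fraction is binomial around the
request, well within ±0.1 for the lengths the tests use (50–300 codons).

## Numerical and degenerate-input choices

* Frequencies are serialized with six decimal places, which round-trips
  every table the package produces bit-exactly; parsing accepts any
  decimal.
* All sequence input is case-insensitive; U is normalized to T everywhere.
* Ambiguous bases (N and friends) in a *coding* sequence are rejected with
  their offset — frequency lookup and synonymy are undefined for them.
  (They are of course legal in enzyme recognition patterns.)
* A sequence whose length is not a multiple of three is an error under the
  default `strict` frame policy; the explicit `trim` policy drops one or
  two trailing bases with a warning.
* Percentages are held at full precision and rounded to one decimal only
  in reports.
* FASTA input is single-record by design (the workflow is one CDS at a
  time); plain-text input strips digits and whitespace so numbered
  editor output pastes cleanly.

## Problem sizes in the test-suite

The guarantees are checked at: 1,000 seeded fixtures × 3 strategies for
protein conservation; 100–200 fixtures for one-click optimality and
idempotence (every position brute-force verified); 200 random sequences up
to 2 kb × 20 enzymes for scanner/oracle agreement; and 25–50 random
instances per serialization round-trip. These sizes give full coverage of
the deterministic properties while keeping the default test run fast.

## Known limitations

* Single-criterion frequency replacement: no joint optimization of GC
  content, motif avoidance or mRNA structure.
* No detection or preservation of slow-translating rare-codon clusters;
  the codon-by-codon mode is the manual escape hatch.
* No computation of usage tables from genome annotations, and no
  codon-bias statistics (CAI, ENC); tables come from the user.
* No ribosome-binding-site or splice-motif checks.
* Rarity is re-annotated statelessly on every call; there is no session
  that remembers a mid-run table edit.
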