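# codonsmith

Rare-codon identification and synonymous codon optimization of coding DNA
sequences, for anyone preparing a gene for heterologous expression (for
example a human CDS to be produced in *Escherichia coli*).

## The problem and the method

Synonymous codons are not used equally within a genome. When a codon that is
frequent in the source organism is rare in the expression host, translation
can stall, reducing yield and solubility. The remedy is *codon
optimization*: silently replacing rare codons with synonyms the host prefers.

codonsmith classifies every codon of a CDS against a host codon usage table
(frequencies in permille, i.e. occurrences per 1,000 codons) using the
two-tier scheme standard in the field:

* **rare** — used at frequency *f* with 5 < *f* < 10 ‰,
* **highly rare** — *f* ≤ 5 ‰,
* **common** — *f* ≥ 10 ‰.

and offers three optimization strategies:

1. **one-click** — every rare and highly rare codon is replaced by the
   most frequently used synonymous codon (ties broken alphabetically);
2. **bulk** — every occurrence of one chosen codon is replaced by one chosen
   synonym, which may deliberately be *rarer* (e.g. to slow translation
   locally);
3. **codon-by-codon** — individual positions are edited one at a time, the
   way one breaks same-codon clusters or removes a restriction site by
   silent mutation.

All three strategies guarantee the encoded protein is unchanged; every run
verifies original-vs-optimized translations and reports any mismatch.
Usage tables are read in both plain-text layouts used by the Codon Usage
Database (Kazusa): the frequency-only layout and the amino-acid-annotated
layout. An annotated table may define a non-standard genetic code, which is
then used for synonym families and translation. The package also computes
G+C / A+T content, and scans both strands for restriction-enzyme
recognition sites (IUPAC ambiguity codes) against a bundled catalogue of
over 100 common commercial enzymes.

## Worked example

```r
library(codonsmith)

tab <- example_usage_table()                       # bundled E. coli-style table
fx  <- generate_fixture(40, rare_fraction = 0.3, seed = 7)
res <- one_click_optimize(fx, tab)
rep <- build_report(fx, tab, result = res, enzymes = c("EcoRI", "BamHI"))
cat(render_report(rep, "text"))
```

prints (abridged):

```
-- Input sequence (rare codons [XXX], highly rare [[XXX]]) --
ATG GCC CAT [TGC] [CAC] [CCT] ACG CTT AAA [AGT] CTG [[ATA]] [TCG] GGC [TCA]
...
Input composition:  120 bases | A 22  C 39  G 32  T 27 | G+C 59.2 %  A+T 40.8 %

-- Optimized sequence (one_click) --
ATG GCC CAT [TGC] CAT CCG ACG CTT AAA AGC CTG ATT AGC GGC AGC
...
Output composition: 120 bases | A 23  C 39  G 36  T 22 | G+C 62.5 %  A+T 37.5 %

-- Substitutions (0-based codon position) --
     4  CAC -> CAT
     5  CCT -> CCG
     9  AGT -> AGC
...
-- Protein alignment --
  original : MAHCHPTLKSLISGSNRYPAELPGRLRVRIGVTPSELVG*
```

Rare codons are bracketed: `[TGC]` is rare, `[[ATA]]` highly rare. After
one-click optimization 13 positions were substituted and the proteins align
identically. `[TGC]` remains marked in the output: both cysteine codons are
below 10 ‰ in this host, so no synonym can make the position common — the
report is honest about such family-wide-rare positions rather than hiding
them.

A command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/codonsmith.R optimize --seq gene.fasta --table usage.txt \
    --mode one-click --enzymes EcoRI,BamHI --out optimized.fasta --report report.txt
```

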