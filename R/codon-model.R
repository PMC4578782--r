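# Codon usage tables, the genetic code, and the two-tier rarity classifier.

#' All 64 codons in canonical order
#'
#' Canonical order is the order of [Biostrings::GENETIC_CODE]: first base
#' slowest, bases ordered T, C, A, G. All tables and codes in this package
#' store their entries in this order.
#'
#' @return Character vector of the 64 DNA codons.
#' @export
all_codons <- function() {
  names(Biostrings::GENETIC_CODE)
}

#' Normalize codon text to canonical DNA form
#'
#' Accepts upper or lower case and RNA (U) alphabet; returns upper-case DNA
#' triplets. Vectorized.
#'
#' @param x character vector of 3-letter codons.
#' @return Character vector of canonical codons (upper case, T alphabet).
#' @export
normalize_codon <- function(x) {
  out <- chartr("U", "T", toupper(as.character(x)))
  bad <- is.na(out) | !grepl("^[ACGT]{3}$", out)
  if (any(bad)) {
    cs_stop("illegal_character", "not a valid codon: '%s'", x[which(bad)[1]])
  }
  out
}

#' Rarity classification thresholds
#'
#' The two-tier scheme expresses usage in per-thousand (permille) units:
#' codons used at or below `highly_rare_upper_permille` are *highly rare*,
#' codons strictly between the two thresholds are *rare*, and codons at or
#' above `rare_upper_permille` are *common*. Defaults follow the widely used
#' 10 / 5 permille convention for heterologous expression hosts.
#'
#' @param rare_upper_permille upper (exclusive) bound of the rare tier.
#' @param highly_rare_upper_permille upper (inclusive) bound of the highly
#'   rare tier. Must be strictly between 0 and `rare_upper_permille`.
#' @return An object of class `rarity_thresholds`.
#' @export
rarity_thresholds <- function(rare_upper_permille = 10,
                              highly_rare_upper_permille = 5) {
  r <- as.numeric(rare_upper_permille)
  h <- as.numeric(highly_rare_upper_permille)
  if (length(r) != 1L || length(h) != 1L || is.na(r) || is.na(h) ||
      !(0 < h && h < r)) {
    cs_stop("invalid_thresholds",
            "thresholds must satisfy 0 < highly_rare (%s) < rare (%s)",
            format(h), format(r))
  }
  structure(list(rare_upper_permille = r, highly_rare_upper_permille = h),
            class = "rarity_thresholds")
}

#' Classify usage frequencies into common / rare / highly rare
#'
#' A frequency f (permille) is `"highly_rare"` when f <= the highly-rare
#' threshold, `"rare"` when it lies strictly between the thresholds, and
#' `"common"` when f >= the rare threshold. With the defaults, 10 permille is
#' already common and 5 permille is still highly rare; the tiers partition
#' the frequency axis.
#'
#' @param frequency_permille numeric vector of non-negative frequencies.
#' @param thresholds a [rarity_thresholds()] object.
#' @return Character vector over `c("common", "rare", "highly_rare")`.
#' @examples
#' classify_rarity(c(0, 5, 7.3, 10, 52.6))
#' @export
classify_rarity <- function(frequency_permille,
                            thresholds = rarity_thresholds()) {
  stopifnot(inherits(thresholds, "rarity_thresholds"))
  f <- as.numeric(frequency_permille)
  if (any(is.na(f))) cs_stop("negative_frequency", "frequency must be numeric")
  if (any(f < 0)) {
    cs_stop("negative_frequency", "negative frequency: %s",
            format(f[f < 0][1]))
  }
  ifelse(f <= thresholds$highly_rare_upper_permille, "highly_rare",
         ifelse(f < thresholds$rare_upper_permille, "rare", "common"))
}

#' The standard genetic code
#'
#' The standard nuclear code as a named character vector mapping all 64 DNA
#' codons to 1-letter amino-acid symbols, with `'*'` for the three stops.
#'
#' @return An object of class `genetic_code`.
#' @examples
#' code <- standard_genetic_code()
#' code["ATG"]  # "M"
#' @export
standard_genetic_code <- function() {
  new_genetic_code(as.character(Biostrings::GENETIC_CODE),
                   names(Biostrings::GENETIC_CODE),
                   name = "standard")
}

new_genetic_code <- function(aa, codons, name) {
  codons <- normalize_codon(codons)
  aa <- toupper(as.character(aa))
  if (length(aa) != 64L || length(unique(codons)) != 64L) {
    cs_stop("missing_codons", "a genetic code must map all 64 codons")
  }
  if (!any(aa == "*")) {
    cs_stop("no_stop_codon", "genetic code defines no stop codon ('*')")
  }
  map <- stats::setNames(aa, codons)[all_codons()]
  structure(map, name = name, class = "genetic_code")
}

#' Derive a genetic code from an amino-acid-annotated usage table
#'
#' Tables in the amino-acid-annotated dialect carry the codon-to-amino-acid
#' assignment alongside the frequencies; reading the code from the table is
#' how non-standard genetic codes enter the pipeline (translation and
#' synonym families then follow the table's code, not the standard one).
#'
#' @param table a [parse_usage_table()] result in the annotated dialect.
#' @return An object of class `genetic_code`.
#' @export
code_from_annotated_table <- function(table) {
  stopifnot(inherits(table, "codon_usage_table"))
  if (is.null(table$amino_acids)) {
    cs_stop("dialect_without_amino_acids",
            "table was parsed from the frequency-only dialect; no amino-acid column")
  }
  new_genetic_code(unname(table$amino_acids), names(table$amino_acids),
                   name = paste0("from table: ", table$organism_label))
}

#' Synonym family of a codon
#'
#' All codons (including `codon` itself) encoding the same amino acid under
#' `code`, in lexicographic order.
#'
#' @param code a `genetic_code`.
#' @param codon a codon (DNA or RNA alphabet, any case).
#' @return Character vector of codons.
#' @examples
#' synonyms(standard_genetic_code(), "GCT")  # the alanine 4-fold box
#' @export
synonyms <- function(code, codon) {
  stopifnot(inherits(code, "genetic_code"))
  codon <- normalize_codon(codon)
  sort(names(code)[code == code[[codon]]])
}

# ---- usage-table parsing ----------------------------------------------------

RE_TRIPLET <- "^[ACGTUacgtu]{3}$"
RE_NUMBER  <- "^[0-9]+\\.?[0-9]*$"
RE_AA      <- "^[A-Za-z*]$"

#' Parse a codon usage table in Codon Usage Database text layout
#'
#' Reads the plain-text table layout users copy from the Codon Usage
#' Database (Kazusa) in either of its two dialects, auto-detected:
#'
#' * **frequency-only** — records of the form `UUU 17.6( 714298)`, several
#'   per line; the parenthesized count is optional.
#' * **amino-acid-annotated** — records of the form
#'   `UUU F 0.58 17.6 ( 714298)` carrying the amino acid and the
#'   within-family fraction.
#'
#' RNA (U) and DNA (T) triplets, arbitrary whitespace and any number of
#' records per line are accepted. Because users may edit tables freely,
#' frequencies are not required to sum to 1000: a table whose 64 frequencies
#' sum within +-1 of 1000 is flagged `consistent`, any other sum merely
#' clears the flag. Structural defects (missing codons, conflicting
#' duplicates, malformed records) are errors.
#'
#' @param text the raw table text (single string or character vector of lines).
#' @param organism_label free-text label stored on the table.
#' @return An object of class `codon_usage_table`: a list with elements
#'   `frequency` (named numeric, all 64 codons, permille), `count` (named
#'   integer or NULL), `amino_acids` (named character or NULL),
#'   `source_dialect` (`"frequency_only"` or `"amino_acid_annotated"`),
#'   `consistent` (logical) and `organism_label`.
#' @examples
#' txt <- serialize_usage_table(example_usage_table(), "frequency")
#' tab <- parse_usage_table(txt)
#' tab$frequency["CTG"]
#' @export
parse_usage_table <- function(text, organism_label = "") {
  if (length(text) == 0L || all(!nzchar(trimws(text)))) {
    cs_stop("empty_input", "usage table text is empty")
  }
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))

  rec_codon <- character()
  rec_aa    <- character()
  rec_freq  <- numeric()
  rec_count <- numeric()
  dialect   <- NA_character_

  for (ln in seq_along(lines)) {
    if (grepl("^[[:space:]]*#", lines[[ln]])) next  # comment lines
    toks <- strsplit(gsub("[()]", " ", lines[[ln]]), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    i <- 1L
    while (i <= length(toks)) {
      if (!grepl(RE_TRIPLET, toks[i])) {
        cs_stop("malformed_record",
                "line %d: expected a codon triplet, got '%s'", ln, toks[i])
      }
      codon <- toks[i]; i <- i + 1L
      annotated <- i <= length(toks) && grepl(RE_AA, toks[i]) &&
        !grepl(RE_NUMBER, toks[i])
      if (is.na(dialect)) {
        dialect <- if (annotated) "amino_acid_annotated" else "frequency_only"
      } else if (annotated != (dialect == "amino_acid_annotated")) {
        cs_stop("malformed_record",
                "line %d: record for %s mixes table dialects", ln, codon)
      }
      if (annotated) {
        # <aa> <fraction> <freq> [<count>]
        if (i + 2L > length(toks) || !grepl(RE_NUMBER, toks[i + 1L]) ||
            !grepl(RE_NUMBER, toks[i + 2L])) {
          cs_stop("malformed_record",
                  "line %d: truncated annotated record for %s", ln, codon)
        }
        aa <- toupper(toks[i])
        freq <- as.numeric(toks[i + 2L])
        i <- i + 3L
      } else {
        if (i > length(toks) || !grepl(RE_NUMBER, toks[i])) {
          cs_stop("malformed_record",
                  "line %d: codon %s not followed by a frequency", ln, codon)
        }
        aa <- NA_character_
        freq <- as.numeric(toks[i])
        i <- i + 1L
      }
      count <- NA_real_
      if (i <= length(toks) && grepl(RE_NUMBER, toks[i])) {
        count <- as.numeric(toks[i])
        i <- i + 1L
      }
      rec_codon <- c(rec_codon, normalize_codon(codon))
      rec_aa    <- c(rec_aa, aa)
      rec_freq  <- c(rec_freq, freq)
      rec_count <- c(rec_count, count)
    }
  }

  dup <- unique(rec_codon[duplicated(rec_codon)])
  for (d in dup) {
    if (length(unique(rec_freq[rec_codon == d])) > 1L) {
      cs_stop("duplicate_codon",
              "codon %s appears more than once with differing frequencies", d)
    }
  }
  keep <- !duplicated(rec_codon)
  rec_codon <- rec_codon[keep]; rec_aa <- rec_aa[keep]
  rec_freq <- rec_freq[keep]; rec_count <- rec_count[keep]

  missing <- setdiff(all_codons(), rec_codon)
  if (length(missing) > 0L) {
    cs_stop("missing_codons", "table is missing %d codon(s): %s",
            length(missing), paste(missing, collapse = ", "))
  }

  ord <- match(all_codons(), rec_codon)
  freq <- stats::setNames(rec_freq[ord], all_codons())
  counts <- if (all(is.na(rec_count))) NULL else
    stats::setNames(rec_count[ord], all_codons())
  aas <- if (dialect == "amino_acid_annotated")
    stats::setNames(rec_aa[ord], all_codons()) else NULL

  new_codon_usage_table(freq, counts, aas, dialect, organism_label)
}

new_codon_usage_table <- function(frequency, count = NULL, amino_acids = NULL,
                                  source_dialect = "frequency_only",
                                  organism_label = "") {
  if (any(frequency < 0)) {
    cs_stop("negative_frequency", "usage frequencies must be non-negative")
  }
  structure(list(
    frequency      = frequency,
    count          = count,
    amino_acids    = amino_acids,
    source_dialect = source_dialect,
    consistent     = abs(sum(frequency) - 1000) <= 1.0,
    organism_label = organism_label
  ), class = "codon_usage_table")
}

#' Build a usage table from a named frequency vector
#'
#' Programmatic constructor, mainly for simulated tables: takes frequencies
#' in permille for all 64 codons (names in any case / alphabet).
#'
#' @param frequency named numeric vector, one entry per codon.
#' @param organism_label free-text label.
#' @return A `codon_usage_table`.
#' @export
usage_table <- function(frequency, organism_label = "") {
  codons <- normalize_codon(names(frequency))
  if (length(unique(codons)) != length(codons)) {
    cs_stop("duplicate_codon", "duplicated codon in frequency vector")
  }
  missing <- setdiff(all_codons(), codons)
  if (length(missing) > 0L) {
    cs_stop("missing_codons", "frequency vector is missing: %s",
            paste(missing, collapse = ", "))
  }
  freq <- stats::setNames(as.numeric(frequency), codons)[all_codons()]
  new_codon_usage_table(freq, organism_label = organism_label)
}

fmt_num <- function(x) {
  sub("\\.$", "", sub("0+$", "", sprintf("%.6f", x)))
}

#' Serialize a usage table back to Codon Usage Database text
#'
#' Emits text that [parse_usage_table()] reads back to an identical frequency
#' mapping (frequencies are written with six decimal places, enough to
#' round-trip any table this package produces). The annotated dialect adds
#' the amino-acid column and the within-family usage fraction computed under
#' `code`.
#'
#' @param table a `codon_usage_table`.
#' @param dialect `"frequency"` or `"annotated"`.
#' @param code genetic code used for the amino-acid column of the annotated
#'   dialect (the table's own code if it has one, else the standard code).
#' @return A single string of table text, four records per line.
#' @export
serialize_usage_table <- function(table, dialect = c("frequency", "annotated"),
                                  code = NULL) {
  stopifnot(inherits(table, "codon_usage_table"))
  if (!is.character(dialect) ||
      !dialect[1] %in% c("frequency", "annotated")) {
    cs_stop("unsupported_dialect", "unknown table dialect: '%s'",
            paste(dialect[1], collapse = ""))
  }
  dialect <- dialect[1]
  if (is.null(code)) {
    code <- if (!is.null(table$amino_acids))
      code_from_annotated_table(table) else standard_genetic_code()
  }
  codons <- all_codons()
  freq <- table$frequency
  cnt <- table$count
  recs <- vapply(codons, function(cd) {
    cstr <- if (!is.null(cnt) && !is.na(cnt[[cd]]))
      sprintf("(%d)", as.integer(round(cnt[[cd]]))) else ""
    if (dialect == "frequency") {
      paste0(cd, " ", fmt_num(freq[[cd]]), cstr)
    } else {
      fam <- names(code)[code == code[[cd]]]
      tot <- sum(freq[fam])
      frac <- if (tot > 0) freq[[cd]] / tot else 0
      paste0(cd, " ", code[[cd]], " ", sprintf("%.2f", frac), " ",
             fmt_num(freq[[cd]]), if (nzchar(cstr)) paste0(" ", cstr) else "")
    }
  }, character(1))
  rows <- split(recs, ceiling(seq_along(recs) / 4))
  paste(vapply(rows, paste, character(1), collapse = "  "), collapse = "\n")
}

#' Bundled example usage table (E. coli style)
#'
#' The example table shipped under `inst/extdata/`, an *Escherichia coli*
#' K-12 style codon usage table in the frequency-only dialect.
#'
#' @return A `codon_usage_table`.
#' @export
example_usage_table <- function() {
  path <- system.file("extdata", "ecoli_usage.txt", package = "codonsmith")
  parse_usage_table(readLines(path), organism_label = "Escherichia coli K-12 (example)")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("Codon usage table%s [%s dialect]%s\n",
              if (nzchar(x$organism_label)) paste0(": ", x$organism_label) else "",
              sub("_", "-", x$source_dialect),
              if (x$consistent) "" else "  (frequencies do not sum to 1000)"))
  cat(sprintf("  64 codons, sum = %s permille\n", fmt_num(sum(x$frequency))))
  invisible(x)
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("Genetic code '%s': %d codons, stops: %s\n",
              attr(x, "name"), length(x),
              paste(names(x)[x == "*"], collapse = ", ")))
  invisible(x)
}
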