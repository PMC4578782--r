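# Base-composition statistics, translation and protein verification, and
# restriction-site scanning against the bundled enzyme catalogue.

#' Base composition of a nucleotide sequence
#'
#' Exact per-base counts plus G+C and A+T content. Percentages are held at
#' full precision; report renderers round to one decimal.
#'
#' @param x nucleotide text or a `coding_sequence`.
#' @return An object of class `sequence_stats`: list with `n_bases`,
#'   `counts` (named integer, A/C/G/T), `gc_percent`, `at_percent`.
#' @examples
#' compute_stats("ATGC")$gc_percent
#' @export
compute_stats <- function(x) {
  s <- if (inherits(x, "coding_sequence")) sequence_text(x) else
    normalize_bases(x)
  if (!nzchar(s)) cs_stop("empty_input", "sequence is empty")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("A", "C", "G", "T"))) {
    cs_stop("illegal_character", "sequence contains non-ACGT characters")
  }
  counts <- vapply(c(A = "A", C = "C", G = "G", T = "T"),
                   function(b) sum(chars == b), integer(1))
  n <- length(chars)
  structure(list(
    n_bases = n,
    counts = counts,
    gc_percent = 100 * (counts[["G"]] + counts[["C"]]) / n,
    at_percent = 100 * (counts[["A"]] + counts[["T"]]) / n
  ), class = "sequence_stats")
}

#' @export
print.sequence_stats <- function(x, ...) {
  cat(sprintf("%d bases | A %d  C %d  G %d  T %d | G+C %.1f%%  A+T %.1f%%\n",
              x$n_bases, x$counts[["A"]], x$counts[["C"]], x$counts[["G"]],
              x$counts[["T"]], x$gc_percent, x$at_percent))
  invisible(x)
}

#' Translate a coding sequence
#'
#' One amino-acid symbol per codon, including internal and terminal stops
#' (`'*'`); no stop truncation is performed, so the translation length always
#' equals the codon count.
#'
#' @param seq a `coding_sequence`.
#' @param code a `genetic_code`.
#' @return Single amino-acid string.
#' @examples
#' translate_cds(decompose("ATGGCTTAA"))  # "MA*"
#' @export
translate_cds <- function(seq, code = standard_genetic_code()) {
  stopifnot(inherits(seq, "coding_sequence"), inherits(code, "genetic_code"))
  paste(unname(code[seq$codons]), collapse = "")
}

#' Compare the proteins encoded by two same-length coding sequences
#'
#' Position-by-position comparison of the two translations (the sequences of
#' an optimization pair always have equal codon counts, so no gapped
#' alignment is needed). A length mismatch signals that the inputs were not
#' an original/optimized pair and is an error.
#'
#' @param original,optimized `coding_sequence` objects of equal codon count.
#' @param code a `genetic_code`.
#' @return An object of class `alignment_report`: list with
#'   `original_protein`, `optimized_protein`, `identical`,
#'   `mismatch_positions` (0-based).
#' @export
compare_proteins <- function(original, optimized,
                             code = standard_genetic_code()) {
  stopifnot(inherits(original, "coding_sequence"),
            inherits(optimized, "coding_sequence"))
  if (length(original$codons) != length(optimized$codons)) {
    cs_stop("length_mismatch",
            "codon counts differ (%d vs %d); not an original/optimized pair",
            length(original$codons), length(optimized$codons))
  }
  p1 <- translate_cds(original, code)
  p2 <- translate_cds(optimized, code)
  a1 <- strsplit(p1, "", fixed = TRUE)[[1]]
  a2 <- strsplit(p2, "", fixed = TRUE)[[1]]
  mism <- which(a1 != a2) - 1L
  structure(list(
    original_protein = p1,
    optimized_protein = p2,
    identical = length(mism) == 0L,
    mismatch_positions = mism
  ), class = "alignment_report")
}

# ---- restriction-site scanning ----------------------------------------------

IUPAC_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

#' Load the bundled restriction-enzyme catalogue
#'
#' Reads the tab-separated catalogue of common commercially available
#' restriction endonucleases shipped under `inst/extdata/` (name and IUPAC
#' recognition sequence, `#` comments). The bundled file carries well over
#' 100 uniquely named enzymes.
#'
#' @param path catalogue file; defaults to the bundled one.
#' @return A data.frame with columns `name` and `recognition`.
#' @export
load_enzyme_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "restriction_enzymes.tsv",
                        package = "codonsmith")
  }
  cat_df <- utils::read.delim(path, comment.char = "#",
                              stringsAsFactors = FALSE)
  if (!all(c("name", "recognition") %in% names(cat_df))) {
    cs_stop("catalogue_corrupt", "catalogue lacks name/recognition columns")
  }
  cat_df$recognition <- toupper(cat_df$recognition)
  if (anyDuplicated(cat_df$name)) {
    cs_stop("catalogue_corrupt", "duplicate enzyme name: %s",
            cat_df$name[duplicated(cat_df$name)][1])
  }
  chars <- strsplit(cat_df$recognition, "", fixed = TRUE)
  ok <- vapply(chars, function(ch)
    length(ch) >= 4L && all(ch %in% IUPAC_ALPHABET), logical(1))
  if (!all(ok)) {
    cs_stop("catalogue_corrupt", "invalid recognition sequence for %s",
            cat_df$name[!ok][1])
  }
  cat_df[, c("name", "recognition")]
}

#' Reverse complement of nucleotide text
#'
#' IUPAC ambiguity codes are complemented correctly (R <-> Y etc.).
#'
#' @param text nucleotide text (may contain ambiguity codes).
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(text) {
  s <- chartr("U", "T", toupper(gsub("[[:space:]]", "", text)))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Scan a sequence for restriction-enzyme recognition sites
#'
#' Finds every match of each enzyme's recognition pattern, expanding IUPAC
#' ambiguity codes (N matches any base, R matches A/G, ...). Both strands
#' are scanned: reverse-strand matches are located by matching the
#' reverse-complemented pattern against the input strand and are reported
#' with `strand = "reverse"` but coordinates on the input strand.
#' Palindromic recognition sequences are reported once per location (forward
#' only). Overlapping matches are all reported. Hits are sorted by start
#' position, then enzyme name.
#'
#' The catalogue-driven report layer checks at most two enzymes per run;
#' this function itself accepts any number.
#'
#' @param sequence_text nucleotide text or a `coding_sequence`.
#' @param enzymes enzyme names (looked up in `catalogue`) or a data.frame
#'   with `name` and `recognition` columns.
#' @param catalogue an enzyme catalogue data.frame; defaults to the bundled
#'   one.
#' @return A data.frame of hits: `enzyme`, `start` (0-based), `end`
#'   (exclusive), `strand` (`"forward"`/`"reverse"`), `matched` (the input
#'   substring).
#' @examples
#' find_sites("AAGAATTCAA", "EcoRI")
#' @export
find_sites <- function(sequence_text, enzymes,
                       catalogue = load_enzyme_catalogue()) {
  s <- if (inherits(sequence_text, "coding_sequence"))
    sequence_text(sequence_text) else normalize_bases(sequence_text)
  if (!nzchar(s)) cs_stop("empty_input", "sequence is empty")

  if (is.character(enzymes)) {
    unknown <- setdiff(enzymes, catalogue$name)
    if (length(unknown) > 0L) {
      cs_stop("unknown_enzyme", "enzyme(s) not in catalogue: %s",
              paste(unknown, collapse = ", "))
    }
    enzymes <- catalogue[match(enzymes, catalogue$name), ]
  }
  stopifnot(is.data.frame(enzymes),
            all(c("name", "recognition") %in% names(enzymes)))

  subject <- Biostrings::DNAString(s)
  hits <- lapply(seq_len(nrow(enzymes)), function(i) {
    nm <- enzymes$name[i]
    pat <- enzymes$recognition[i]
    rc <- reverse_complement(pat)
    fwd <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
    out <- data.frame(
      enzyme = rep(nm, length(fwd)),
      start = BiocGenerics::start(fwd) - 1L,
      end = BiocGenerics::end(fwd),
      strand = rep("forward", length(fwd)),
      stringsAsFactors = FALSE
    )
    if (rc != pat) {  # non-palindromic: scan the reverse strand too
      rev <- Biostrings::matchPattern(rc, subject, fixed = FALSE)
      out <- rbind(out, data.frame(
        enzyme = rep(nm, length(rev)),
        start = BiocGenerics::start(rev) - 1L,
        end = BiocGenerics::end(rev),
        strand = rep("reverse", length(rev)),
        stringsAsFactors = FALSE
      ))
    }
    out
  })
  out <- do.call(rbind, hits)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(enzyme = character(), start = integer(),
                      end = integer(), strand = character(),
                      matched = character(), stringsAsFactors = FALSE))
  }
  out$matched <- substring(s, out$start + 1L, out$end)
  out <- out[order(out$start, out$enzyme, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
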