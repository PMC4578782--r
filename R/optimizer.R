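# Coding sequences, per-codon rarity annotation, and the three optimization
# strategies. Every strategy returns an optimization_result whose optimized
# sequence is guaranteed to translate to the same protein as the original.

#' Construct a coding sequence from codons
#'
#' @param codons character vector of codons (normalized on input).
#' @param header free-text header (FASTA description), may be empty.
#' @return An object of class `coding_sequence`.
#' @export
coding_sequence <- function(codons, header = "") {
  if (length(codons) == 0L) cs_stop("empty_input", "no codons")
  structure(list(header = as.character(header)[1],
                 codons = normalize_codon(codons)),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("Coding sequence%s: %d codons (%d nt)\n",
              if (nzchar(x$header)) paste0(" '", x$header, "'") else "",
              length(x$codons), 3L * length(x$codons)))
  cat(" ", substr(sequence_text(x), 1, 60),
      if (length(x$codons) > 20) "...\n" else "\n")
  invisible(x)
}

#' Nucleotide text of a coding sequence
#' @param seq a `coding_sequence`.
#' @return Single string of concatenated codons.
#' @export
sequence_text <- function(seq) {
  stopifnot(inherits(seq, "coding_sequence"))
  paste(seq$codons, collapse = "")
}

normalize_bases <- function(text) {
  chartr("U", "T", toupper(gsub("[[:space:]]", "", paste(text, collapse = ""))))
}

#' Decompose nucleotide text into a coding sequence
#'
#' Reads codons 5'-to-3' from the first base. Case and RNA/DNA alphabet are
#' normalized; whitespace is ignored. Under the default `"strict"` frame
#' policy a length that is not a multiple of three is an error; under
#' `"trim"` one or two trailing bases are dropped with a warning.
#'
#' @param sequence_text nucleotide text.
#' @param frame_policy `"strict"` or `"trim"`.
#' @param header header to attach to the result.
#' @return A `coding_sequence`.
#' @examples
#' decompose("augGCUuaa")$codons
#' @export
decompose <- function(sequence_text, frame_policy = c("strict", "trim"),
                      header = "") {
  frame_policy <- match.arg(frame_policy)
  s <- normalize_bases(sequence_text)
  if (!nzchar(s)) cs_stop("empty_input", "sequence is empty")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    cs_stop("illegal_character",
            "illegal character '%s' at base %d (ambiguity codes are not accepted)",
            chars[bad[1]], bad[1])
  }
  extra <- length(chars) %% 3L
  if (extra != 0L) {
    if (frame_policy == "strict") {
      cs_stop("not_coding_frame",
              "sequence length %d is not a multiple of 3 (use frame_policy = 'trim' to drop trailing bases)",
              length(chars))
    }
    cs_warn("trimmed", "dropped %d trailing base(s) to restore the frame", extra)
    chars <- chars[seq_len(length(chars) - extra)]
  }
  n <- length(chars) / 3L
  codons <- vapply(seq_len(n), function(i)
    paste(chars[(3L * i - 2L):(3L * i)], collapse = ""), character(1))
  coding_sequence(codons, header = header)
}

#' Annotate each codon with its usage frequency and rarity tier
#'
#' @param seq a `coding_sequence`.
#' @param table a `codon_usage_table`.
#' @param code a `genetic_code`.
#' @param thresholds a [rarity_thresholds()] object.
#' @return A data.frame with one row per codon position: `index` (0-based),
#'   `codon`, `amino_acid`, `frequency_permille`, `rarity`.
#' @export
annotate_codons <- function(seq, table, code = standard_genetic_code(),
                            thresholds = rarity_thresholds()) {
  stopifnot(inherits(seq, "coding_sequence"),
            inherits(table, "codon_usage_table"),
            inherits(code, "genetic_code"))
  freq <- unname(table$frequency[seq$codons])
  data.frame(
    index = seq_along(seq$codons) - 1L,
    codon = seq$codons,
    amino_acid = unname(code[seq$codons]),
    frequency_permille = freq,
    rarity = classify_rarity(freq, thresholds),
    stringsAsFactors = FALSE
  )
}

# Maximum-frequency synonym for each of the 64 codons; frequency ties break
# lexicographically on the codon text so results are deterministic.
best_synonyms <- function(table, code) {
  vapply(all_codons(), function(cd) {
    fam <- synonyms(code, cd)            # lexicographically sorted
    fam[which.max(table$frequency[fam])] # which.max takes the first tie
  }, character(1))
}

new_optimization_result <- function(original, optimized, substitutions,
                                    strategy, code) {
  structure(list(
    original = original,
    optimized = optimized,
    substitutions = substitutions,
    strategy = strategy,
    translation_verified = identical(translate_cds(original, code),
                                     translate_cds(optimized, code))
  ), class = "optimization_result")
}

empty_substitutions <- function() {
  data.frame(index = integer(), from_codon = character(),
             to_codon = character(), stringsAsFactors = FALSE)
}

make_result <- function(seq, new_codons, strategy, code) {
  changed <- which(new_codons != seq$codons)
  subs <- if (length(changed) == 0L) empty_substitutions() else
    data.frame(index = changed - 1L,
               from_codon = seq$codons[changed],
               to_codon = new_codons[changed],
               stringsAsFactors = FALSE)
  new_optimization_result(seq, coding_sequence(new_codons, seq$header),
                          subs, strategy, code)
}

#' One-click optimization
#'
#' Replaces every rare and highly rare codon with the most frequently used
#' synonymous codon in the table (frequency ties broken lexicographically).
#' Common codons are untouched; a rare codon that already is its family's
#' frequency maximum stays as it is, so the output can legitimately retain
#' rare codons when an entire synonym family is below threshold (tryptophan
#' in a low-TGG host, for instance). The encoded protein never changes, and
#' the operation is idempotent.
#'
#' @inheritParams annotate_codons
#' @return An `optimization_result`: list with the original and optimized
#'   `coding_sequence`, a `substitutions` data.frame (`index`, `from_codon`,
#'   `to_codon`), the `strategy` tag and `translation_verified`.
#' @export
one_click_optimize <- function(seq, table, code = standard_genetic_code(),
                               thresholds = rarity_thresholds()) {
  ann <- annotate_codons(seq, table, code, thresholds)
  best <- best_synonyms(table, code)
  new_codons <- ifelse(ann$rarity == "common", seq$codons,
                       unname(best[seq$codons]))
  make_result(seq, new_codons, "one_click", code)
}

#' Bulk per-codon-type replacement
#'
#' Replaces every occurrence of `from_codon` with the synonymous `to_codon`
#' of the user's choice -- which may have a *lower* usage frequency than the
#' original (deliberately slowing translation at those positions is a valid
#' use). Replacing a codon with itself is a no-op, not an error.
#'
#' @param seq a `coding_sequence`.
#' @param from_codon,to_codon synonymous codons under `code`.
#' @param code a `genetic_code`.
#' @return An `optimization_result`.
#' @export
bulk_replace <- function(seq, from_codon, to_codon,
                         code = standard_genetic_code()) {
  stopifnot(inherits(seq, "coding_sequence"), inherits(code, "genetic_code"))
  from_codon <- normalize_codon(from_codon)
  to_codon <- normalize_codon(to_codon)
  if (code[[from_codon]] != code[[to_codon]]) {
    cs_stop("not_synonymous",
            "%s (%s) and %s (%s) are not synonymous; replacement would change the protein",
            from_codon, code[[from_codon]], to_codon, code[[to_codon]])
  }
  new_codons <- ifelse(seq$codons == from_codon, to_codon, seq$codons)
  make_result(seq, new_codons, "bulk", code)
}

#' Replace the codon at a single position
#'
#' Codon-by-codon editing: changes exactly one position to a synonymous
#' codon. This is the mechanism for breaking same-codon clusters and for
#' creating or destroying restriction sites through silent mutations.
#'
#' @param seq a `coding_sequence`.
#' @param index 0-based codon position.
#' @param to_codon replacement codon, synonymous with the current one.
#' @param code a `genetic_code`.
#' @return An `optimization_result`.
#' @export
set_codon <- function(seq, index, to_codon, code = standard_genetic_code()) {
  stopifnot(inherits(seq, "coding_sequence"), inherits(code, "genetic_code"))
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) || index < 0L ||
      index >= length(seq$codons)) {
    cs_stop("index_out_of_range",
            "codon index %s outside [0, %d]", format(index),
            length(seq$codons) - 1L)
  }
  to_codon <- normalize_codon(to_codon)
  cur <- seq$codons[index + 1L]
  if (code[[cur]] != code[[to_codon]]) {
    cs_stop("not_synonymous",
            "cannot set position %d: %s (%s) -> %s (%s) would change the protein",
            index, cur, code[[cur]], to_codon, code[[to_codon]])
  }
  new_codons <- seq$codons
  new_codons[index + 1L] <- to_codon
  make_result(seq, new_codons, "by_codon", code)
}

#' Synonymous alternatives for a codon, ranked by usage
#'
#' All synonyms of `codon` (itself included), sorted by descending table
#' frequency with lexicographic tie-break, each with its frequency and
#' rarity tier. The first row is the codon [one_click_optimize()] would
#' choose at a rare position.
#'
#' @param codon a codon.
#' @param table a `codon_usage_table`.
#' @param code a `genetic_code`.
#' @param thresholds a [rarity_thresholds()] object.
#' @return A data.frame with columns `codon`, `frequency_permille`, `rarity`.
#' @export
alternatives <- function(codon, table, code = standard_genetic_code(),
                         thresholds = rarity_thresholds()) {
  stopifnot(inherits(table, "codon_usage_table"))
  fam <- synonyms(code, codon)
  freq <- unname(table$frequency[fam])
  ord <- order(-freq, fam)
  data.frame(codon = fam[ord],
             frequency_permille = freq[ord],
             rarity = classify_rarity(freq[ord], thresholds),
             stringsAsFactors = FALSE)
}

#' Replay a substitution log onto a sequence
#'
#' Applies the `substitutions` data.frame of an [one_click_optimize()] /
#' [bulk_replace()] / [set_codon()] result to a sequence; replaying a
#' result's log onto its original reproduces its optimized sequence exactly.
#'
#' @param seq a `coding_sequence`.
#' @param substitutions data.frame with `index`, `from_codon`, `to_codon`.
#' @return A `coding_sequence`.
#' @export
apply_substitutions <- function(seq, substitutions) {
  stopifnot(inherits(seq, "coding_sequence"))
  codons <- seq$codons
  if (nrow(substitutions) > 0L) {
    idx <- substitutions$index + 1L
    if (any(codons[idx] != substitutions$from_codon)) {
      cs_stop("substitution_mismatch",
              "substitution log does not match the sequence at some position")
    }
    codons[idx] <- substitutions$to_codon
  }
  coding_sequence(codons, seq$header)
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("Optimization result (%s): %d codons, %d substitution(s), protein %s\n",
              x$strategy, length(x$original$codons), nrow(x$substitutions),
              if (x$translation_verified) "conserved" else "CHANGED"))
  invisible(x)
}
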