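# Shared fixtures and independent brute-force oracles. The oracles here are
# written from first principles (plain loops over offsets / positions) so
# they share no code with the implementation they check.

# A reproducible random usage table: positive frequencies, one decimal.
random_usage_table <- function(seed, lo = 0.5, hi = 50) {
  withr::with_seed(seed, {
    usage_table(stats::setNames(round(stats::runif(64, lo, hi), 1),
                                all_codons()),
                organism_label = paste0("random-", seed))
  })
}

# Uniform random codon sequence (may contain internal stops; fine for
# translation and scanning tests).
random_cds <- function(n, seed) {
  withr::with_seed(seed, {
    coding_sequence(sample(all_codons(), n, replace = TRUE))
  })
}

# A table in which every synonym family has at least one clearly common
# member: family maxima get 30 permille, the rest 2 permille.
table_with_common_synonyms <- function(code = standard_genetic_code()) {
  freq <- stats::setNames(rep(2, 64), all_codons())
  for (aa in unique(code)) {
    fam <- sort(names(code)[code == aa])
    freq[fam[1]] <- 30
  }
  usage_table(freq)
}

# ---- IUPAC scanning oracle --------------------------------------------------

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", V = "B", D = "H", H = "D", N = "N")

oracle_revcomp <- function(pattern) {
  ch <- rev(strsplit(pattern, "", fixed = TRUE)[[1]])
  paste(unname(IUPAC_COMPLEMENT[ch]), collapse = "")
}

# Test every offset of `s` against the expanded base sets of `pattern`.
oracle_match_offsets <- function(s_chars, pattern) {
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  L <- length(pat)
  n <- length(s_chars)
  if (n < L) return(integer())
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    ok <- ok & s_chars[j:(n - L + j)] %in% IUPAC_SETS[[pat[j]]]
  }
  which(ok)  # 1-based start offsets
}

oracle_find_sites <- function(sequence_text, enzymes) {
  s_chars <- strsplit(sequence_text, "", fixed = TRUE)[[1]]
  rows <- list()
  for (i in seq_len(nrow(enzymes))) {
    nm <- enzymes$name[i]
    pat <- enzymes$recognition[i]
    rc <- oracle_revcomp(pat)
    L <- nchar(pat)
    for (st in oracle_match_offsets(s_chars, pat)) {
      rows[[length(rows) + 1L]] <-
        data.frame(enzyme = nm, start = st - 1L, end = st - 1L + L,
                   strand = "forward", stringsAsFactors = FALSE)
    }
    if (rc != pat) {
      for (st in oracle_match_offsets(s_chars, rc)) {
        rows[[length(rows) + 1L]] <-
          data.frame(enzyme = nm, start = st - 1L, end = st - 1L + L,
                     strand = "reverse", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(enzyme = character(), start = integer(),
                      end = integer(), strand = character(),
                      matched = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$matched <- substring(sequence_text, out$start + 1L, out$end)
  out <- out[order(out$start, out$enzyme, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Independent rarity count: plain loop, re-stating the tier definition.
oracle_rare_count <- function(codons, freq, rare = 10, highly = 5) {
  n <- 0L
  for (cd in codons) {
    f <- freq[[cd]]
    if (f <= highly || f < rare) n <- n + 1L
  }
  n
}
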