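# Sequence I/O, report rendering, the seeded fixture generator, and the
# pipeline runner behind the command-line interface.

#' Read a coding sequence from FASTA or plain text
#'
#' If `input` names an existing file its content is read; otherwise `input`
#' is treated as literal text. Content starting with `>` is parsed as
#' single-record FASTA (the header is retained; multi-record input is an
#' error asking the user to split the file). Anything else is treated as raw
#' bases. Whitespace and digits are stripped, so numbered output pasted from
#' sequence editors is accepted; any other non-nucleotide character is an
#' error with its offset.
#'
#' @param input path to a file, or sequence text.
#' @param frame_policy passed to [decompose()]: `"strict"` (default) errors
#'   on a length that is not a multiple of 3, `"trim"` drops 1-2 trailing
#'   bases with a warning.
#' @return A `coding_sequence`.
#' @examples
#' read_sequence(">gene1\nATGGCT\nTAA")$header
#' @export
read_sequence <- function(input, frame_policy = c("strict", "trim")) {
  frame_policy <- match.arg(frame_policy)
  txt <- input
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    txt <- readLines(input, warn = FALSE)
  }
  lines <- unlist(strsplit(paste(txt, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    cs_stop("empty_input", "no sequence found in input")
  }
  header <- ""
  if (startsWith(trimws(lines[1]), ">")) {
    headers <- grep("^>", trimws(lines))
    if (length(headers) > 1L) {
      cs_stop("multi_record_fasta",
              "input contains %d FASTA records; supply one coding sequence at a time",
              length(headers))
    }
    header <- sub("^>", "", trimws(lines[1]))
    body <- paste(lines[-1], collapse = "")
  } else {
    body <- paste(lines, collapse = "")
  }
  body <- gsub("[[:digit:][:space:]]", "", body)
  decompose(body, frame_policy = frame_policy, header = header)
}

#' Write a coding sequence as single-record FASTA
#'
#' 60 bases per line; `read_sequence()` reads the file back to an identical
#' sequence.
#'
#' @param seq a `coding_sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "coding_sequence"))
  s <- sequence_text(seq)
  starts <- seq(1L, nchar(s), by = 60L)
  lines <- c(paste0(">", seq$header),
             substring(s, starts, pmin(starts + 59L, nchar(s))))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) cs_stop("io_failure", "cannot write FASTA to '%s'", path)
  invisible(path)
}

# ---- fixture generation -----------------------------------------------------

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a reproducible random coding sequence
#'
#' Draws a seeded random CDS that starts with ATG and ends with the table's
#' most frequent stop codon. Each interior position is rare with probability
#' `rare_fraction`: rare positions draw uniformly from the non-stop codons
#' classified rare or highly rare under `table`, the rest draw from the
#' common ones. For sequences of realistic length the realized rare fraction
#' is therefore within about +-0.1 of the request. Used by the examples and
#' the test-suite as a stand-in for user sequences.
#'
#' @param n_codons total codon count including start and stop; at least 2.
#' @param rare_fraction target fraction of rare codons, in \[0, 1\].
#' @param seed integer seed; the same seed always yields the same sequence.
#' @param table a `codon_usage_table`.
#' @param code a `genetic_code`.
#' @param thresholds a [rarity_thresholds()] object.
#' @return A `coding_sequence`.
#' @export
generate_fixture <- function(n_codons, rare_fraction = 0.2, seed = 1L,
                             table = example_usage_table(),
                             code = standard_genetic_code(),
                             thresholds = rarity_thresholds()) {
  n_codons <- as.integer(n_codons)
  if (is.na(n_codons) || n_codons < 2L) {
    cs_stop("invalid_argument",
            "n_codons must be >= 2 (a start and a stop codon)")
  }
  if (rare_fraction < 0 || rare_fraction > 1) {
    cs_stop("invalid_argument", "rare_fraction must be in [0, 1]")
  }
  rarity <- classify_rarity(table$frequency, thresholds)
  non_stop <- names(code)[code != "*"]
  rare_pool <- intersect(names(table$frequency)[rarity != "common"], non_stop)
  common_pool <- intersect(names(table$frequency)[rarity == "common"], non_stop)
  if (rare_fraction > 0 && length(rare_pool) == 0L) {
    cs_stop("infeasible_fraction", "table has no rare non-stop codons to draw from")
  }
  if (rare_fraction < 1 && length(common_pool) == 0L) {
    cs_stop("infeasible_fraction", "table has no common non-stop codons to draw from")
  }
  stops <- names(code)[code == "*"]
  stop_codon <- stops[order(-table$frequency[stops], stops)][1]
  interior <- with_seed(seed, {
    k <- n_codons - 2L
    if (k == 0L) character() else {
      is_rare <- stats::runif(k) < rare_fraction
      out <- character(k)
      out[is_rare] <- sample(rare_pool, sum(is_rare), replace = TRUE)
      out[!is_rare] <- sample(common_pool, sum(!is_rare), replace = TRUE)
      out
    }
  })
  coding_sequence(c("ATG", interior, stop_codon),
                  header = sprintf("fixture n=%d rare=%.2f seed=%d",
                                   n_codons, rare_fraction, seed))
}

# ---- reports ----------------------------------------------------------------

#' Assemble an analysis report
#'
#' Collects everything a run produces -- rarity-annotated input (and, after
#' optimization, output), substitution log, base-composition statistics,
#' protein alignment, usage-table display and restriction-site hits -- into
#' one object that [render_report()] turns into text or HTML.
#'
#' @param original a `coding_sequence`.
#' @param table a `codon_usage_table`.
#' @param code a `genetic_code`.
#' @param thresholds a [rarity_thresholds()] object.
#' @param result optional `optimization_result` for `original`.
#' @param enzymes optional character vector of at most two catalogue enzyme
#'   names to scan for.
#' @param catalogue enzyme catalogue; defaults to the bundled one.
#' @return An object of class `codon_report`.
#' @export
build_report <- function(original, table, code = standard_genetic_code(),
                         thresholds = rarity_thresholds(), result = NULL,
                         enzymes = NULL, catalogue = load_enzyme_catalogue()) {
  stopifnot(inherits(original, "coding_sequence"))
  if (!is.null(enzymes) && length(enzymes) > 2L) {
    cs_stop("too_many_enzymes",
            "at most two enzymes can be checked per report (%d given)",
            length(enzymes))
  }
  ann_in <- annotate_codons(original, table, code, thresholds)
  optimized <- if (!is.null(result)) result$optimized else NULL
  ann_out <- if (!is.null(optimized))
    annotate_codons(optimized, table, code, thresholds) else NULL
  scan_target <- if (!is.null(optimized)) optimized else original
  hits <- if (!is.null(enzymes) && length(enzymes) > 0L)
    find_sites(scan_target, enzymes, catalogue) else NULL
  alignment <- if (!is.null(optimized))
    compare_proteins(original, optimized, code) else NULL
  structure(list(
    original = original,
    optimized = optimized,
    annotated_original = ann_in,
    annotated_optimized = ann_out,
    substitutions = if (!is.null(result)) result$substitutions else NULL,
    strategy = if (!is.null(result)) result$strategy else NULL,
    stats_in = compute_stats(original),
    stats_out = if (!is.null(optimized)) compute_stats(optimized) else NULL,
    alignment = alignment,
    table = table,
    thresholds = thresholds,
    enzymes = enzymes,
    site_hits = hits
  ), class = "codon_report")
}

mark_codons_text <- function(ann) {
  marked <- ifelse(ann$rarity == "highly_rare",
                   paste0("[[", ann$codon, "]]"),
                   ifelse(ann$rarity == "rare",
                          paste0("[", ann$codon, "]"), ann$codon))
  rows <- split(marked, ceiling(seq_along(marked) / 15))
  paste(vapply(rows, paste, character(1), collapse = " "), collapse = "\n")
}

stats_line <- function(st) {
  sprintf("%d bases | A %d  C %d  G %d  T %d | G+C %.1f %%  A+T %.1f %%",
          st$n_bases, st$counts[["A"]], st$counts[["C"]], st$counts[["G"]],
          st$counts[["T"]], st$gc_percent, st$at_percent)
}

render_text_report <- function(r) {
  out <- c("=== Codon analysis report ===", "")
  if (nzchar(r$original$header)) out <- c(out, paste("Sequence:", r$original$header), "")
  out <- c(out,
           "-- Input sequence (rare codons [XXX], highly rare [[XXX]]) --",
           mark_codons_text(r$annotated_original),
           paste("Input composition: ", stats_line(r$stats_in)), "")
  if (!is.null(r$annotated_optimized)) {
    out <- c(out,
             sprintf("-- Optimized sequence (%s) --", r$strategy),
             mark_codons_text(r$annotated_optimized),
             paste("Output composition:", stats_line(r$stats_out)), "")
    if (nrow(r$substitutions) > 0L) {
      out <- c(out, "-- Substitutions (0-based codon position) --",
               sprintf("  %4d  %s -> %s", r$substitutions$index,
                       r$substitutions$from_codon, r$substitutions$to_codon), "")
    } else {
      out <- c(out, "-- Substitutions --", "  none", "")
    }
    out <- c(out, "-- Protein alignment --",
             paste("  original :", r$alignment$original_protein),
             paste("  optimized:", r$alignment$optimized_protein),
             if (r$alignment$identical) "  proteins identical" else
               paste("  MISMATCH at 0-based position(s):",
                     paste(r$alignment$mismatch_positions, collapse = ", ")),
             "")
  }
  if (!is.null(r$site_hits)) {
    out <- c(out, sprintf("-- Restriction sites (%s) --",
                          paste(r$enzymes, collapse = ", ")))
    if (nrow(r$site_hits) == 0L) {
      out <- c(out, "  none found", "")
    } else {
      h <- r$site_hits
      out <- c(out, sprintf("  %-10s %6d..%-6d %-7s %s", h$enzyme,
                            h$start + 1L, h$end, h$strand, h$matched), "")
    }
  }
  rar <- classify_rarity(r$table$frequency, r$thresholds)
  tag <- ifelse(rar == "highly_rare", " (highly rare)",
                ifelse(rar == "rare", " (rare)", ""))
  recs <- sprintf("%s %s%s", names(r$table$frequency),
                  vapply(unname(r$table$frequency), fmt_num, character(1)), tag)
  rows <- split(recs, ceiling(seq_along(recs) / 4))
  out <- c(out, "-- Usage data (permille) --",
           vapply(rows, paste, character(1), collapse = "   "))
  paste(out, collapse = "\n")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

mark_codons_html <- function(ann) {
  span <- ifelse(ann$rarity == "highly_rare",
                 paste0("<span class=\"hrare\" style=\"color:red\">",
                        ann$codon, "</span>"),
                 ifelse(ann$rarity == "rare",
                        paste0("<span class=\"rare\" style=\"color:orange\">",
                               ann$codon, "</span>"),
                        ann$codon))
  paste(span, collapse = " ")
}

render_html_report <- function(r) {
  body <- c("<h1>Codon analysis report</h1>")
  if (nzchar(r$original$header)) {
    body <- c(body, paste0("<p>Sequence: ", html_escape(r$original$header), "</p>"))
  }
  body <- c(body, "<h2>Input sequence</h2>",
            paste0("<p class=\"seq\">", mark_codons_html(r$annotated_original), "</p>"),
            paste0("<p>", html_escape(stats_line(r$stats_in)), "</p>"))
  if (!is.null(r$annotated_optimized)) {
    body <- c(body, "<h2>Optimized sequence</h2>",
              paste0("<p class=\"seq\">", mark_codons_html(r$annotated_optimized), "</p>"),
              paste0("<p>", html_escape(stats_line(r$stats_out)), "</p>"),
              "<h2>Protein alignment</h2>",
              paste0("<pre>", html_escape(r$alignment$original_protein), "\n",
                     html_escape(r$alignment$optimized_protein), "</pre>"),
              paste0("<p>", if (r$alignment$identical) "proteins identical"
                     else "PROTEIN MISMATCH", "</p>"))
  }
  if (!is.null(r$site_hits) && nrow(r$site_hits) > 0L) {
    h <- r$site_hits
    body <- c(body, "<h2>Restriction sites</h2>", "<ul>",
              sprintf("<li>%s %d..%d (%s) %s</li>", html_escape(h$enzyme),
                      h$start + 1L, h$end, h$strand, h$matched),
              "</ul>")
  }
  paste(c("<!DOCTYPE html>", "<html><head><title>Codon analysis report</title></head><body>",
          body, "</body></html>"), collapse = "\n")
}

#' Render a report as plain text or HTML
#'
#' The text format marks rare codons as `[XXX]` and highly rare codons as
#' `[[XXX]]`; the HTML format uses orange and red spans for the same two
#' tiers. Both embed the composition statistics, the substitution log, the
#' protein alignment, restriction-site hits and the usage-table display.
#' Site positions are rendered 1-based inclusive, the convention molecular
#' biologists read.
#'
#' @param report a `codon_report` from [build_report()].
#' @param format `"text"` or `"html"`.
#' @return A single string.
#' @export
render_report <- function(report, format = c("text", "html")) {
  stopifnot(inherits(report, "codon_report"))
  if (!is.character(format) || !format[1] %in% c("text", "html")) {
    cs_stop("unsupported_format", "unknown report format '%s'",
            paste(format[1], collapse = ""))
  }
  if (format[1] == "text") render_text_report(report) else
    render_html_report(report)
}

#' @export
print.codon_report <- function(x, ...) {
  cat(render_text_report(x), "\n")
  invisible(x)
}

# ---- pipeline ---------------------------------------------------------------

#' Validated run configuration for the pipeline
#'
#' @param sequence sequence file path or literal sequence text.
#' @param table usage-table file path or literal table text.
#' @param mode `"annotate"`, `"one_click"`, `"bulk"` or `"by_codon"`.
#' @param bulk_from,bulk_to codons for `"bulk"` mode.
#' @param edits for `"by_codon"` mode: list of `c(position, codon)` pairs or
#'   strings `"POS:CODON"` (0-based positions).
#' @param enzymes at most two catalogue enzyme names.
#' @param thresholds a [rarity_thresholds()] object.
#' @param frame_policy `"strict"` or `"trim"`.
#' @param out_fasta optional path for the optimized FASTA.
#' @param report_path optional path for the rendered report.
#' @param report_format `"text"` or `"html"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sequence, table, mode = c("annotate", "one_click",
                                                 "bulk", "by_codon"),
                       bulk_from = NULL, bulk_to = NULL, edits = NULL,
                       enzymes = NULL, thresholds = rarity_thresholds(),
                       frame_policy = c("strict", "trim"),
                       out_fasta = NULL, report_path = NULL,
                       report_format = c("text", "html")) {
  mode <- match.arg(mode)
  frame_policy <- match.arg(frame_policy)
  if (!report_format[1] %in% c("text", "html")) {
    cs_stop("unsupported_format", "unknown report format '%s'", report_format[1])
  }
  if (mode == "bulk" && (is.null(bulk_from) || is.null(bulk_to))) {
    cs_stop("invalid_config", "bulk mode requires bulk_from and bulk_to codons")
  }
  if (mode == "by_codon" && (is.null(edits) || length(edits) == 0L)) {
    cs_stop("invalid_config", "by_codon mode requires at least one edit")
  }
  if (!is.null(enzymes) && length(enzymes) > 2L) {
    cs_stop("too_many_enzymes", "at most two enzymes per run (%d given)",
            length(enzymes))
  }
  if (!is.null(edits)) {
    if (is.character(edits)) edits <- as.list(edits)
    edits <- lapply(edits, function(e) {
      if (is.character(e) && length(e) == 1L && grepl(":", e)) {
        parts <- strsplit(e, ":", fixed = TRUE)[[1]]
        e <- c(parts[1], parts[2])
      }
      pos <- suppressWarnings(as.integer(e[[1]]))
      if (is.na(pos)) cs_stop("invalid_config", "bad edit position '%s'", e[[1]])
      list(index = pos, codon = as.character(e[[2]]))
    })
  }
  structure(list(sequence = sequence, table = table, mode = mode,
                 bulk_from = bulk_from, bulk_to = bulk_to, edits = edits,
                 enzymes = enzymes, thresholds = thresholds,
                 frame_policy = frame_policy, out_fasta = out_fasta,
                 report_path = report_path, report_format = report_format[1]),
            class = "run_config")
}

read_table_input <- function(x) {
  if (inherits(x, "codon_usage_table")) return(x)
  txt <- x
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    txt <- readLines(x, warn = FALSE)
  }
  parse_usage_table(txt)
}

#' Run the full analysis pipeline
#'
#' Executes parse, annotate, the selected optimization strategy, protein
#' verification, composition statistics, restriction-site scan and report
#' rendering, then writes the requested artifacts. Nothing is written until
#' the whole computation has succeeded, so output files are never partial.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the `report` object, the rendered report
#'   string, the `optimization_result` (NULL in annotate mode) and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seq <- read_sequence(config$sequence, frame_policy = config$frame_policy)
  table <- read_table_input(config$table)
  code <- if (!is.null(table$amino_acids)) code_from_annotated_table(table)
          else standard_genetic_code()

  result <- switch(config$mode,
    annotate = NULL,
    one_click = one_click_optimize(seq, table, code, config$thresholds),
    bulk = bulk_replace(seq, config$bulk_from, config$bulk_to, code),
    by_codon = {
      cur <- seq
      subs <- empty_substitutions()
      for (e in config$edits) {
        step <- set_codon(cur, e$index, e$codon, code)
        subs <- rbind(subs, step$substitutions)
        cur <- step$optimized
      }
      new_optimization_result(seq, cur, subs, "by_codon", code)
    })

  report <- build_report(seq, table, code, config$thresholds, result,
                         config$enzymes)
  rendered <- render_report(report, config$report_format)

  written <- character()
  if (!is.null(result) && !is.null(config$out_fasta)) {
    write_sequence(result$optimized, config$out_fasta)
    written <- c(written, config$out_fasta)
  }
  if (!is.null(config$report_path)) {
    writeLines(rendered, config$report_path)
    written <- c(written, config$report_path)
  }
  invisible(list(report = report, rendered = rendered, result = result,
                 paths = written))
}
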