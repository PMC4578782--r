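# FASTA / plain-text I/O, report rendering, fixture generation and the
# end-to-end pipeline.

test_that("sequence input accepts FASTA and tolerant plain text", {
  s <- read_sequence(">gene1\nATGGCT\nTAA")
  expect_identical(s$header, "gene1")
  expect_identical(s$codons, c("ATG", "GCT", "TAA"))

  s2 <- read_sequence("atg gct taa")
  expect_identical(s2$header, "")
  expect_identical(s2$codons, c("ATG", "GCT", "TAA"))

  # numbered editor output: digits and whitespace are stripped
  s3 <- read_sequence("1 ATGGCT\n7 TAA")
  expect_identical(s3$codons, c("ATG", "GCT", "TAA"))

  expect_error(read_sequence(">a\nATG\n>b\nGCT"),
               class = "codonsmith_error_multi_record_fasta")
  expect_error(read_sequence("ATG-GCT"),
               class = "codonsmith_error_illegal_character")
  expect_error(read_sequence("\n\n"), class = "codonsmith_error_empty_input")
})

test_that("FASTA writing wraps at 60 columns and round-trips", {
  s <- generate_fixture(61, 0.2, seed = 3)
  path <- tempfile(fileext = ".fasta")
  write_sequence(s, path)
  lines <- readLines(path)
  expect_identical(lines[1], paste0(">", s$header))
  expect_equal(nchar(lines[2]), 60)
  expect_equal(sum(nchar(lines[-1])), 3 * 61)

  for (seed in 1:8) {
    s <- random_cds(withr::with_seed(seed, sample(5:80, 1)), seed)
    p <- tempfile(fileext = ".fasta")
    write_sequence(s, p)
    back <- read_sequence(p)
    expect_identical(back$codons, s$codons)
    expect_identical(back$header, s$header)
  }
})

test_that("fixtures are seed-reproducible and hit the requested rare fraction", {
  a <- generate_fixture(100, 0.3, seed = 11)
  b <- generate_fixture(100, 0.3, seed = 11)
  expect_identical(a$codons, b$codons)
  expect_false(identical(a$codons, generate_fixture(100, 0.3, seed = 12)$codons))
  expect_identical(a$codons[1], "ATG")
  expect_true(standard_genetic_code()[[a$codons[100]]] == "*")

  tab <- example_usage_table()
  for (seed in 1:40) {
    fx <- generate_fixture(200, 0.25, seed = seed, table = tab)
    frac <- mean(annotate_codons(fx, tab)$rarity != "common")
    expect_lt(abs(frac - 0.25), 0.1)
  }
})

test_that("a zero rare fraction yields a clean sequence when the table allows", {
  # stops included: give the stop family a common member too
  freq <- table_with_common_synonyms()$frequency
  fx <- generate_fixture(60, 0, seed = 5, table = usage_table(freq))
  expect_equal(sum(annotate_codons(fx, usage_table(freq))$rarity != "common"), 0)
})

test_that("infeasible fixture requests are rejected", {
  all_common <- usage_table(stats::setNames(rep(15.625, 64), all_codons()))
  expect_error(generate_fixture(50, 0.5, seed = 1, table = all_common),
               class = "codonsmith_error_infeasible_fraction")
  all_rare <- usage_table(stats::setNames(rep(2, 64), all_codons()))
  expect_error(generate_fixture(50, 0.5, seed = 1, table = all_rare),
               class = "codonsmith_error_infeasible_fraction")
  expect_error(generate_fixture(1, 0.5, seed = 1),
               class = "codonsmith_error_invalid_argument")
})

count_text_marks <- function(txt) {
  # count [XXX] and [[XXX]] marks in the sequence sections only
  sections <- strsplit(txt, "\n-- ")[[1]]
  seqs <- grep("sequence", sections, value = TRUE)
  body <- paste(seqs, collapse = "\n")
  hr <- gregexpr("\\[\\[[ACGT]{3}\\]\\]", body)[[1]]
  n_hr <- sum(hr > 0)
  r <- gregexpr("(?<!\\[)\\[[ACGT]{3}\\](?!\\])", body, perl = TRUE)[[1]]
  n_r <- sum(r > 0)
  c(rare = n_r, highly_rare = n_hr)
}

test_that("rendered rarity marks agree with the annotation engine", {
  tab <- example_usage_table()
  for (seed in c(2, 9)) {
    fx <- generate_fixture(80, 0.3, seed = seed, table = tab)
    res <- one_click_optimize(fx, tab)
    rep <- build_report(fx, tab, result = res, enzymes = c("EcoRI", "BamHI"))
    txt <- render_report(rep, "text")
    ann <- rbind(annotate_codons(fx, tab), annotate_codons(res$optimized, tab))
    marks <- count_text_marks(txt)
    expect_equal(unname(marks["rare"]), sum(ann$rarity == "rare"))
    expect_equal(unname(marks["highly_rare"]), sum(ann$rarity == "highly_rare"))
  }

  # no rare codons -> no marks anywhere in the sequence sections
  clean_tab <- table_with_common_synonyms()
  fx <- generate_fixture(30, 0, seed = 1, table = clean_tab)
  rep0 <- build_report(fx, clean_tab)
  expect_identical(unname(count_text_marks(render_report(rep0, "text"))), c(0L, 0L))
})

test_that("HTML reports are well-formed and carry the two-tier styling", {
  tab <- example_usage_table()
  fx <- generate_fixture(50, 0.4, seed = 21, table = tab)
  res <- one_click_optimize(fx, tab)
  html <- render_report(build_report(fx, tab, result = res,
                                     enzymes = "EcoRI"), "html")
  doc <- xml2::read_html(html)
  expect_s3_class(doc, "xml_document")
  ann <- annotate_codons(fx, tab)
  spans_r <- xml2::xml_find_all(doc, "//span[@class='rare']")
  spans_h <- xml2::xml_find_all(doc, "//span[@class='hrare']")
  expect_gte(length(spans_r) + length(spans_h), sum(ann$rarity != "common"))
  expect_error(render_report(build_report(fx, tab), "pdf"),
               class = "codonsmith_error_unsupported_format")
})

test_that("the pipeline runs end-to-end for every mode", {
  tab_path <- system.file("extdata", "ecoli_usage.txt", package = "codonsmith")
  fx <- generate_fixture(60, 0.3, seed = 8)
  seq_path <- tempfile(fileext = ".fasta")
  write_sequence(fx, seq_path)

  # annotate: report only, no FASTA written
  out1 <- tempfile(fileext = ".txt")
  r1 <- run_pipeline(run_config(seq_path, tab_path, mode = "annotate",
                                report_path = out1))
  expect_true(file.exists(out1))
  expect_null(r1$result)

  # one-click: written FASTA translates identically to the input
  fa <- tempfile(fileext = ".fasta")
  r2 <- run_pipeline(run_config(seq_path, tab_path, mode = "one_click",
                                out_fasta = fa, enzymes = c("EcoRI", "BamHI")))
  expect_true(r2$result$translation_verified)
  expect_identical(translate_cds(read_sequence(fa)), translate_cds(fx))

  # bulk and by-codon modes
  from <- fx$codons[2]
  to <- synonyms(standard_genetic_code(), from)[1]
  r3 <- run_pipeline(run_config(seq_path, tab_path, mode = "bulk",
                                bulk_from = from, bulk_to = to))
  expect_true(r3$result$translation_verified)
  r4 <- run_pipeline(run_config(seq_path, tab_path, mode = "by_codon",
                                edits = sprintf("1:%s", to)))
  expect_true(r4$result$translation_verified)
  expect_equal(r4$result$optimized$codons[2], to)

  # config validation fires before any I/O
  expect_error(run_config(seq_path, tab_path, mode = "bulk"),
               class = "codonsmith_error_invalid_config")
  expect_error(run_config(seq_path, tab_path, mode = "by_codon"),
               class = "codonsmith_error_invalid_config")
  expect_error(run_config(seq_path, tab_path, enzymes = c("A", "B", "C")),
               class = "codonsmith_error_too_many_enzymes")
})

test_that("equal configurations give byte-identical artifacts", {
  tab_path <- system.file("extdata", "ecoli_usage.txt", package = "codonsmith")
  fx <- generate_fixture(40, 0.3, seed = 19)
  seq_path <- tempfile(fileext = ".fasta")
  write_sequence(fx, seq_path)
  render <- function() {
    rp <- tempfile(fileext = ".txt"); fa <- tempfile(fileext = ".fasta")
    run_pipeline(run_config(seq_path, tab_path, mode = "one_click",
                            out_fasta = fa, report_path = rp,
                            enzymes = "EcoRI"))
    list(report = readLines(rp), fasta = readLines(fa))
  }
  expect_identical(render(), render())
})
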