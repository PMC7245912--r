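make_ir_record <- function(L = 2000, irb = "300..499", ira = "1500..1699",
                           irb_val = "IRb", ira_val = "IRa",
                           kind = "repeat_region", qual = "note",
                           extra = character()) {
  path <- withr::local_tempfile(fileext = ".gb", .local_envir = parent.frame())
  set.seed(21)
  fl <- c(feat_lines(kind, irb, setNames(irb_val, qual)),
          feat_lines(kind, ira, setNames(ira_val, qual)),
          extra)
  write_test_gb(path, rand_dna(L), feature_lines = fl)
  suppressWarnings(suppressMessages(parse_genbank(path)))
}

test_that("IR annotations are found case-insensitively across qualifier spellings, with misc_feature fallback", {
  rec <- make_ir_record()
  irs <- find_ir_annotations(rec)
  expect_identical(irs$irb$start, 300L)
  expect_identical(irs$ira$end, 1699L)

  # long-form spelling, mixed case
  rec2 <- make_ir_record(irb_val = "inverted repeat B",
                         ira_val = "inverted repeat a")
  irs2 <- find_ir_annotations(rec2)
  expect_identical(irs2$ira$label, "IRa")
  expect_identical(irs2$irb$label, "IRb")

  # misc_feature fallback when no repeat_region carries the values
  rec3 <- make_ir_record(kind = "misc_feature")
  irs3 <- find_ir_annotations(rec3)
  expect_identical(irs3$irb$start, 300L)

  # no repeat annotations at all
  path <- withr::local_tempfile(fileext = ".gb")
  set.seed(22)
  write_test_gb(path, rand_dna(500))
  rec4 <- suppressWarnings(parse_genbank(path))
  expect_message(irs4 <- find_ir_annotations(rec4))
  expect_null(irs4$ira)
  expect_null(irs4$irb)
})

test_that("conflicting annotations for one IR label raise a validation error naming both spans", {
  rec <- make_ir_record(extra = feat_lines("repeat_region", "700..800",
                                           note = "IRb"))
  err <- expect_error(find_ir_annotations(rec),
                      class = "plastocov_validation_error")
  expect_match(conditionMessage(err), "300..499", fixed = TRUE)
  expect_match(conditionMessage(err), "700..800", fixed = TRUE)
})

test_that("derive_partition fills the single-copy gaps between the IRs", {
  rec <- make_ir_record()
  p <- derive_partition(rec, ira = list(label = "IRa", start = 1500L, end = 2000L),
                        irb = list(label = "IRb", start = 300L, end = 499L))
  expect_true(p$has_quadripartite)
  expect_identical(p$regions$label, c("LSC", "IRb", "SSC", "IRa"))
  expect_identical(p$regions$start, c(1L, 300L, 500L, 1500L))
  expect_identical(p$regions$end, c(299L, 499L, 1499L, 2000L))
  expect_identical(sum(p$regions$end - p$regions$start + 1L), rec$length)
})

test_that("fewer than two IRs yields a single WHOLE region", {
  path <- withr::local_tempfile(fileext = ".gb")
  set.seed(23)
  write_test_gb(path, rand_dna(700))
  rec <- suppressWarnings(parse_genbank(path))
  p <- derive_partition(rec, ira = NULL, irb = NULL)
  expect_false(p$has_quadripartite)
  expect_identical(p$regions$label, "WHOLE")
  expect_identical(p$regions$start, 1L)
  expect_identical(p$regions$end, 700L)
})

test_that("a trailing segment after IRa is carried as an extra LSC piece with a warning", {
  path <- withr::local_tempfile(fileext = ".gb")
  set.seed(24)
  write_test_gb(path, rand_dna(1000))
  rec <- suppressWarnings(parse_genbank(path))
  expect_warning(
    p <- derive_partition(rec,
                          ira = list(label = "IRa", start = 700L, end = 899L),
                          irb = list(label = "IRb", start = 300L, end = 499L)),
    class = "plastocov_partition_gap_warning")
  expect_identical(p$regions$label, c("LSC", "IRb", "SSC", "IRa", "LSC"))
  expect_identical(p$regions$start[5], 900L)
  expect_identical(region_of_position(p, c(950L, 1000L)), c("LSC", "LSC"))
  # still covers every position exactly once
  expect_identical(sum(p$regions$end - p$regions$start + 1L), 1000L)
})

test_that("overlapping IRs error; IRa annotated first is honored with a warning", {
  path <- withr::local_tempfile(fileext = ".gb")
  set.seed(25)
  write_test_gb(path, rand_dna(1000))
  rec <- suppressWarnings(parse_genbank(path))
  expect_error(
    derive_partition(rec, ira = list(label = "IRa", start = 450L, end = 700L),
                     irb = list(label = "IRb", start = 300L, end = 499L)),
    class = "plastocov_validation_error")
  expect_warning(
    p <- derive_partition(rec,
                          ira = list(label = "IRa", start = 300L, end = 499L),
                          irb = list(label = "IRb", start = 700L, end = 1000L)),
    class = "plastocov_ir_order_warning")
  expect_identical(p$regions$label, c("LSC", "IRa", "SSC", "IRb"))
})

test_that("every genome position belongs to exactly one region", {
  fx <- default_fixture()
  m <- fixture_model(fx)
  labels <- region_of_position(m$partition, seq_len(m$record$length))
  expect_false(anyNA(labels))
  counts <- table(labels)
  reg <- m$partition$regions
  for (lab in unique(reg$label)) {
    expect_identical(unname(counts[[lab]]),
                     sum(reg$end[reg$label == lab] - reg$start[reg$label == lab] + 1L))
  }
})

test_that("table_region_size reproduces the printed end-minus-start convention", {
  expect_identical(table_region_size(list(start = 90654L, end = 116283L)), 25629L)
  expect_identical(table_region_size(list(start = 5L, end = 5L)), 0L)
  # one less than the inclusive length, by construction
  expect_identical(table_region_size(list(start = 10L, end = 30L)),
                   inclusive_length(list(start = 10L, end = 30L)) - 1L)
})

test_that("collect_genes deduplicates by (name, span), sorts by start, and falls back to CDS/tRNA/rRNA", {
  path <- withr::local_tempfile(fileext = ".gb")
  set.seed(26)
  write_test_gb(path, rand_dna(900), feature_lines = c(
    feat_lines("gene", "500..600", gene = "rpl2"),
    feat_lines("gene", "100..200", gene = "rpl2"),
    feat_lines("gene", "100..200", gene = "rpl2"),   # exact duplicate
    feat_lines("gene", "300..400", gene = "rpl2")))
  rec <- suppressWarnings(parse_genbank(path))
  g <- collect_genes(rec)
  expect_identical(nrow(g), 3L)   # dedup by (name, span), not by name
  expect_identical(g$start, c(100L, 300L, 500L))

  path2 <- withr::local_tempfile(fileext = ".gb")
  write_test_gb(path2, rand_dna(900), feature_lines = c(
    feat_lines("CDS", "100..200", gene = "psbA"),
    feat_lines("tRNA", "300..350", product = "tRNA-His")))
  rec2 <- suppressWarnings(parse_genbank(path2))
  expect_warning(g2 <- collect_genes(rec2),
                 class = "plastocov_gene_fallback_warning")
  expect_identical(nrow(g2), 2L)
})
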