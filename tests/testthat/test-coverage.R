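whole_partition <- function(L) {
  raw_partition(data.frame(label = "WHOLE", start = 1L, end = as.integer(L),
                           stringsAsFactors = FALSE),
                has_quadripartite = FALSE, genome_length = L)
}

quad_partition <- function(bounds) {
  # bounds: integer vector of 4 region lengths
  ends <- cumsum(bounds)
  starts <- c(1L, head(ends, -1L) + 1L)
  raw_partition(data.frame(label = c("LSC", "IRb", "SSC", "IRa"),
                           start = as.integer(starts), end = as.integer(ends),
                           stringsAsFactors = FALSE),
                has_quadripartite = TRUE, genome_length = sum(bounds))
}

random_spans <- function(L, n_max = 200L) {
  n <- sample.int(n_max, 1L)
  s <- sample.int(L, n, replace = TRUE)
  e <- pmin(L, s + sample.int(60L, n, replace = TRUE) - 1L)
  data.frame(start = s, end = e)
}

test_that("sweep_depth handles empty input and a single full-length span", {
  expect_identical(sweep_depth(data.frame(start = integer(), end = integer()), 10),
                   integer(10))
  expect_identical(sweep_depth(data.frame(start = 1L, end = 10L), 10),
                   rep(1L, 10))
  expect_error(sweep_depth(data.frame(start = 0L, end = 5L), 10),
               class = "plastocov_validation_error")
  expect_error(sweep_depth(data.frame(start = 2L, end = 11L), 10),
               class = "plastocov_validation_error")
})

test_that("sweep_depth equals the naive per-position pileup on randomized alignment sets", {
  set.seed(31)
  for (i in 1:30) {
    L <- sample(50:500, 1L)
    spans <- random_spans(L)
    expect_identical(sweep_depth(spans, L), naive_pileup(spans, L))
  }
})

test_that("windowize tiles each region independently with one remainder window", {
  p <- whole_partition(1000L)
  w <- windowize(rep(1L, 1000), p, 250L)
  expect_identical(nrow(w), 4L)
  expect_identical(unique(w$end - w$start + 1L), 250L)

  p2 <- whole_partition(600L)
  w2 <- windowize(rep(0L, 600), p2, 250L)
  expect_identical(w2$end - w2$start + 1L, c(250L, 250L, 100L))

  # region-restarted tiling: no window crosses a boundary, counts follow ceil()
  p3 <- quad_partition(c(520L, 260L, 140L, 260L))
  w3 <- windowize(rep(2L, 1180), p3, 250L)
  counts <- table(factor(w3$region_label, levels = c("LSC", "IRb", "SSC", "IRa")))
  expect_identical(as.integer(counts), as.integer(ceiling(c(520, 260, 140, 260) / 250)))
  expect_identical(region_of_position(p3, w3$start), region_of_position(p3, w3$end))
  # joint exact cover
  expect_identical(sum(w3$end - w3$start + 1L), 1180L)
})

test_that("region means average each region's own positions and weight up to the genome mean", {
  p <- quad_partition(c(400L, 200L, 100L, 200L))
  depth <- rep(7L, 900)
  expect_equal(unname(region_means(depth, p)), rep(7, 4))

  # the single-copy vs inverted-repeat depth contrast seen in real assemblies
  depth2 <- integer(900)
  lab <- region_of_position(p, 1:900)
  depth2[lab %in% c("LSC", "SSC")] <- 20L
  depth2[lab %in% c("IRb", "IRa")] <- 16L
  expect_equal(unname(region_means(depth2, p)[c("LSC", "IRb", "SSC", "IRa")]),
               c(20, 16, 20, 16))

  set.seed(32)
  for (i in 1:20) {
    lens <- sample(50:400, 4L)
    p_i <- quad_partition(lens)
    d <- sample(0:50, sum(lens), replace = TRUE)
    rm <- region_means(d, p_i)
    weighted <- sum(rm[c("LSC", "IRb", "SSC", "IRa")] * lens) / sum(lens)
    expect_equal(weighted, mean(d), tolerance = 1e-12)
  }
})

test_that("flagging uses a strict inequality and is monotone in the threshold", {
  p <- whole_partition(500L)
  w <- windowize(rep(10L, 500), p, 250L)
  w$mean_depth <- c(9.9, 10.0)
  rel <- flag_windows(w, genome_mean = 20,
                      coverage_config(threshold = 0.5))
  expect_identical(rel$flagged, c(TRUE, FALSE))   # 9.9 < 10 but 10.0 is not

  abs_cfg <- coverage_config(threshold = 615, threshold_is_relative = FALSE)
  w$mean_depth <- c(614, 615)
  ab <- flag_windows(w, genome_mean = 1e6, abs_cfg)
  expect_identical(ab$flagged, c(TRUE, FALSE))

  # raising the threshold never unflags a window
  set.seed(33)
  w$mean_depth <- runif(2, 0, 30)
  prev <- rep(FALSE, 2L)
  for (thr in seq(0.05, 2, by = 0.05)) {
    cur <- flag_windows(w, 15, coverage_config(threshold = thr))$flagged
    expect_false(any(prev & !cur))
    prev <- cur
  }
})

test_that("log display transform is log10(x+1), monotone, and leaves flags alone", {
  p <- whole_partition(750L)
  w <- windowize(c(rep(0L, 250), rep(99L, 250), rep(5L, 250)), p, 250L)
  w <- flag_windows(w, genome_mean = mean(c(rep(0, 250), rep(99, 250), rep(5, 250))),
                    coverage_config())
  flags_before <- w$flagged
  lw <- log_transform_depths(w)
  expect_equal(lw$display_depth[1], 0)
  expect_equal(lw$display_depth[2], 2)
  expect_identical(order(lw$display_depth), order(lw$mean_depth))
  expect_identical(lw$flagged, flags_before)
})

test_that("conservation: window totals, per-base sums, and span lengths agree", {
  fx <- default_fixture()
  m <- fixture_model(fx)
  track <- suppressWarnings(
    compute_coverage(m$record, m$partition, bam_path = fx$bam_path))
  expect_identical(sum(track$windows$total), sum(as.numeric(track$per_base)))
  expect_identical(sum(track$windows$total),
                   sum(as.numeric(fx$spans$end - fx$spans$start + 1L)))
  lens <- m$partition$regions$end - m$partition$regions$start + 1L
  by_label <- tapply(lens, m$partition$regions$label, sum)
  weighted <- sum(track$region_means * by_label[names(track$region_means)]) /
    m$record$length
  expect_equal(weighted, track$genome_mean, tolerance = 1e-12)
})

test_that("BAM reading converts coordinates, filters categories, bridges deletions, splits skips", {
  dir <- withr::local_tempdir()
  rec <- bare_record(strrep("ACGT", 50))   # 200 bp
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:200", rec$accession),
           sprintf("r1\t0\t%s\t1\t60\t100M\t*\t0\t0\t*\t*", rec$accession),
           sprintf("r2\t0\t%s\t21\t60\t10M5D10M\t*\t0\t0\t*\t*", rec$accession),
           sprintf("r3\t0\t%s\t41\t60\t10M5N10M\t*\t0\t0\t*\t*", rec$accession),
           sprintf("r4\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"),
           sprintf("r5\t256\t%s\t61\t60\t10M\t*\t0\t0\t*\t*", rec$accession),
           sprintf("r6\t1024\t%s\t71\t60\t10M\t*\t0\t0\t*\t*", rec$accession))
  sam_path <- file.path(dir, "toy.sam")
  writeLines(sam, sam_path)
  Rsamtools::asBam(sam_path, file.path(dir, "toy"), overwrite = TRUE,
                   indexDestination = TRUE)
  spans <- read_spans_from_bam(file.path(dir, "toy.bam"), rec)
  # r1: 0-based pos 0 -> 1..100; r2: deletion bridged 21..45;
  # r3: N split 41..50 and 56..65; r4 unmapped, r5 secondary, r6 duplicate dropped
  expect_identical(spans$start, c(1L, 21L, 41L, 56L))
  expect_identical(spans$end, c(100L, 45L, 50L, 65L))

  # duplicates are counted when removed from the exclusion filter
  spans_dup <- read_spans_from_bam(
    file.path(dir, "toy.bam"), rec,
    coverage_config(flag_filter = c("unmapped", "secondary", "supplementary",
                                    "qcfail")))
  expect_identical(nrow(spans_dup), 5L)
})

test_that("BAM errors: missing index, unmatched reference, length mismatch", {
  dir <- withr::local_tempdir()
  rec <- bare_record(strrep("ACGT", 50))
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:200", rec$accession),
           sprintf("r1\t0\t%s\t1\t60\t50M\t*\t0\t0\t*\t*", rec$accession))
  sam_path <- file.path(dir, "a.sam")
  writeLines(sam, sam_path)
  Rsamtools::asBam(sam_path, file.path(dir, "a"), overwrite = TRUE,
                   indexDestination = FALSE)
  err <- expect_error(read_spans_from_bam(file.path(dir, "a.bam"), rec),
                      class = "plastocov_input_error")
  expect_match(conditionMessage(err), "index")

  # single reference under a different name but matching length is accepted
  sam2 <- sub(rec$accession, "contig_1", sam, fixed = TRUE)
  writeLines(sam2, file.path(dir, "b.sam"))
  Rsamtools::asBam(file.path(dir, "b.sam"), file.path(dir, "b"),
                   overwrite = TRUE, indexDestination = TRUE)
  spans <- read_spans_from_bam(file.path(dir, "b.bam"), rec)
  expect_identical(nrow(spans), 1L)

  # reference length differing from the genome is a validation error
  sam3 <- sub("LN:200", "LN:190", sam, fixed = TRUE)
  sam3 <- sub("50M", "40M", sam3, fixed = TRUE)
  writeLines(sam3, file.path(dir, "c.sam"))
  Rsamtools::asBam(file.path(dir, "c.sam"), file.path(dir, "c"),
                   overwrite = TRUE, indexDestination = TRUE)
  expect_error(read_spans_from_bam(file.path(dir, "c.bam"), rec),
               class = "plastocov_validation_error")
})

test_that("bedGraph and BED exports use 0-based half-open coordinates", {
  p <- whole_partition(500L)
  w <- windowize(rep(3L, 500), p, 250L)
  w <- flag_windows(w, genome_mean = 100, coverage_config())  # everything flagged
  dir <- withr::local_tempdir()
  bg <- readLines(write_bedgraph(w, "chr", file.path(dir, "w.bedgraph")))
  expect_identical(bg[2], "chr\t0\t250\t3")
  bed <- readLines(write_flagged_bed(w, "chr", file.path(dir, "w.bed")))
  expect_identical(length(bed), 2L)
  expect_identical(strsplit(bed[1], "\t")[[1]][2:3], c("0", "250"))
})
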