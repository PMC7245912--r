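# Synthetic fixtures: a fully annotated toy plastome flatfile plus a
# matching coordinate-sorted, indexed BAM with known ground-truth pileup.
# Every module is testable from these without any downloads. The genome is
# built with IRa as the exact reverse complement of IRb (before optional
# perturbations) and a mirrored IR gene roster, including one
# boundary-spanning gene whose IR portion has a mirrored counterpart
# annotation and a duplicated gene name (two trnI copies) per IR.

#' Specification of a synthetic plastome fixture
#'
#' Defaults describe a ~14.8 kb toy genome (deliberately below the 50 kb
#' preferred plastome range, for test speed; the size-range warning is
#' expected) with single-copy regions at 20x and IRs at 16x target depth,
#' mirroring the depth contrast seen in real quadripartite assemblies,
#' plus one coverage dropout spanning two 250 bp windows of the LSC.
#'
#' @param lsc,irb,ssc,ira region lengths in bp.
#' @param depth_sc,depth_ir target coverage depth for single-copy and IR
#'   regions.
#' @param read_length simulated read length in bp.
#' @param seed integer seed; the fixture is deterministic given the spec.
#' @param dropout list of `c(start, end)` intervals receiving zero reads.
#' @param perturbations character subset of `"ir_point_mutation"`,
#'   `"ir_gene_deletion"`, `"ir_length_change"`.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(lsc = 8000L, irb = 2500L, ssc = 1800L, ira = 2500L,
                         depth_sc = 20, depth_ir = 16, read_length = 100L,
                         seed = 101L, dropout = list(c(3001L, 3500L)),
                         perturbations = character()) {
  known <- c("ir_point_mutation", "ir_gene_deletion", "ir_length_change")
  bad <- setdiff(perturbations, known)
  if (length(bad)) {
    pcv_stop(sprintf("unknown perturbation(s): %s", paste(bad, collapse = ", ")),
             "plastocov_spec_error")
  }
  if (irb != ira) {
    pcv_stop("IRb and IRa must have equal length before perturbations",
             "plastocov_spec_error")
  }
  if (min(lsc, irb, ssc, ira) < 1000L) {
    pcv_stop("fixture regions must each be at least 1 kb to fit the gene roster",
             "plastocov_spec_error")
  }
  structure(list(lsc = as.integer(lsc), irb = as.integer(irb),
                 ssc = as.integer(ssc), ira = as.integer(ira),
                 depth_sc = depth_sc, depth_ir = depth_ir,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed), dropout = dropout,
                 perturbations = perturbations),
            class = "fixture_spec")
}

fixture_regions <- function(spec) {
  lsc_end <- spec$lsc
  irb_end <- lsc_end + spec$irb
  ssc_end <- irb_end + spec$ssc
  ira_end <- ssc_end + spec$ira
  data.frame(label = c("LSC", "IRb", "SSC", "IRa"),
             start = c(1L, lsc_end + 1L, irb_end + 1L, ssc_end + 1L),
             end = c(lsc_end, irb_end, ssc_end, ira_end),
             stringsAsFactors = FALSE)
}

# Gene roster in region-relative offsets. The IRa roster is generated by
# mirroring the IRb-resident spans (including the IR portion of the
# boundary-crossing rps19), so gene synteny between the IRs holds by
# construction.
fixture_roster <- function(spec) {
  reg <- fixture_regions(spec)
  at <- function(label) reg[reg$label == label, ]
  lsc <- at("LSC"); irb <- at("IRb"); ira <- at("IRa"); ssc <- at("SSC")
  stopifnot(spec$lsc >= 8000L)  # roster offsets assume the default layout
  genes <- data.frame(
    name = c("psbA", "matK", "rbcL", "trnH", "rps19"),
    start = c(201L, 1500L, 4000L, 6000L, lsc$end - 300L),
    end = c(1100L, 2799L, 5199L, 6079L, lsc$end + 299L),
    strand = c("+", "-", "+", "+", "+"),
    stringsAsFactors = FALSE)
  irb_offsets <- data.frame(   # relative to IRb start, 1-based
    name = c("trnI", "rpl2", "rpl23", "trnI"),
    s = c(350L, 500L, 1700L, 2020L),
    e = c(420L, 1599L, 1979L, 2090L),
    stringsAsFactors = FALSE)
  genes <- rbind(genes, data.frame(
    name = irb_offsets$name,
    start = irb$start - 1L + irb_offsets$s,
    end = irb$start - 1L + irb_offsets$e,
    strand = "+", stringsAsFactors = FALSE))
  genes <- rbind(genes, data.frame(
    name = "ndhF", start = ssc$start + 199L, end = ssc$start + 1499L,
    strand = "-", stringsAsFactors = FALSE))
  # mirrored IRa copies: IRb offset [s..e] maps to IRa offset [w-e+1..w-s+1]
  w <- spec$ira
  mirror <- rbind(irb_offsets,
                  data.frame(name = "rps19", s = 1L, e = 299L))  # IR part of rps19
  genes <- rbind(genes, data.frame(
    name = mirror$name,
    start = ira$start - 1L + (w - mirror$e + 1L),
    end = ira$start - 1L + (w - mirror$s + 1L),
    strand = "-", stringsAsFactors = FALSE))
  genes[order(genes$start), , drop = FALSE]
}

#' Generate the synthetic annotated plastome flatfile
#'
#' Builds the random genome (IRa = reverse complement of IRb before
#' perturbations), annotates the IRs as `repeat_region` features with
#' `/note` qualifier values `"IRb"`/`"IRa"` and the genes per the roster,
#' applies any requested perturbations, and writes a valid single-record
#' GenBank flatfile. Deterministic given the spec (including its seed).
#'
#' @param spec a [fixture_spec()].
#' @param path output flatfile path.
#' @return invisibly, a list with `path`, the ground-truth `record`
#'   (`plastome_record`), and `regions` (the true region table).
#' @export
make_genome <- function(spec, path) {
  stopifnot(inherits(spec, "fixture_spec"))
  reg <- fixture_regions(spec)
  set.seed(spec$seed)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
  lsc_seq <- rand_seq(spec$lsc)
  irb_seq <- rand_seq(spec$irb)
  ssc_seq <- rand_seq(spec$ssc)
  ira_seq <- revcomp(irb_seq)
  genome <- paste0(lsc_seq, irb_seq, ssc_seq, ira_seq)

  ira_row <- reg[reg$label == "IRa", ]
  if ("ir_point_mutation" %in% spec$perturbations) {
    pos <- ira_row$start + spec$ira %/% 2L
    old <- substr(genome, pos, pos)
    substr(genome, pos, pos) <- chartr("ACGT", "CGTA", old)
  }

  ira_ann_start <- ira_row$start
  if ("ir_length_change" %in% spec$perturbations) {
    ira_ann_start <- ira_ann_start + 20L   # IRa annotated 20 bp shorter
  }

  genes <- fixture_roster(spec)
  if ("ir_gene_deletion" %in% spec$perturbations) {
    in_ira <- genes$start >= ira_row$start & genes$name == "rpl23"
    genes <- genes[!in_ira, , drop = FALSE]
  }

  irb_row <- reg[reg$label == "IRb", ]
  n_feat <- 2L + nrow(genes)
  feat <- data.frame(
    kind = c("repeat_region", "repeat_region", rep("gene", nrow(genes))),
    name = c("IRb", "IRa", genes$name),
    start = c(irb_row$start, ira_ann_start, genes$start),
    end = c(irb_row$end, ira_row$end, genes$end),
    strand = c("+", "+", genes$strand),
    group_id = seq_len(n_feat), part = rep(0L, n_feat),
    qualifiers = I(c(list(c(note = "IRb"), c(note = "IRa")),
                     lapply(genes$name, function(n) c(gene = n)))),
    stringsAsFactors = FALSE)
  feat <- feat[order(feat$start, feat$end), , drop = FALSE]
  feat$group_id <- seq_len(nrow(feat))
  record <- new_plastome_record("SYNPL001", "Synthetica plastomica",
                                genome, feat)
  write_genbank(record, path)
  invisible(list(path = path, record = record, regions = reg))
}

#' Generate the matching sorted, indexed BAM with known ground truth
#'
#' Places ungapped, fully matching single-end reads of fixed length at
#' stratified positions within each region (evenly spaced starts with
#' small seeded jitter) so each region closely attains its target depth;
#' dropout intervals receive zero reads. The exact per-base pileup is
#' recorded by naive per-position counting while the alignments are
#' written, giving an oracle that is independent of the sweep algorithm.
#'
#' @param spec a [fixture_spec()].
#' @param genome the list returned by [make_genome()].
#' @param bam_path output BAM path (an ancillary `.bai` index is written
#'   alongside).
#' @return invisibly, a list with `bam_path`, `ground_truth` (integer
#'   per-base pileup), and `spans` (the read span data.frame).
#' @export
make_reads <- function(spec, genome, bam_path) {
  stopifnot(inherits(spec, "fixture_spec"))
  record <- genome$record
  reg <- genome$regions
  rl <- spec$read_length
  set.seed(spec$seed + 1L)
  L <- record$length
  starts <- integer()
  # reads are allowed to run past their region's end into the neighbor, as
  # in a real mapping (regions are annotations, not sequence breaks); only
  # the linear genome ends show coverage ramps
  for (i in seq_len(nrow(reg))) {
    r <- reg[i, ]
    depth <- if (r$label %in% c("LSC", "SSC")) spec$depth_sc else spec$depth_ir
    len <- r$end - r$start + 1L
    n <- round(depth * len / rl)
    base <- round(seq(r$start, min(r$end, L - rl + 1L), length.out = n))
    jit <- sample(-3:3, n, replace = TRUE)
    s <- pmin(pmax(base + jit, 1L), L - rl + 1L)
    starts <- c(starts, s)
  }
  ends <- starts + rl - 1L
  if (length(spec$dropout)) {
    keep <- rep(TRUE, length(starts))
    for (iv in spec$dropout) {
      keep <- keep & (ends < iv[1L] | starts > iv[2L])
    }
    starts <- starts[keep]; ends <- ends[keep]
  }
  # anchor reads flush with the genome ends and the dropout edges, so every
  # position outside a dropout is covered despite placement jitter
  anchors <- c(1L, L - rl + 1L)
  for (iv in spec$dropout) {
    anchors <- c(anchors, iv[1L] - rl, iv[2L] + 1L)
  }
  anchors <- anchors[anchors >= 1L & anchors <= L - rl + 1L]
  if (length(spec$dropout)) {
    ok <- rep(TRUE, length(anchors))
    for (iv in spec$dropout) {
      ok <- ok & (anchors + rl - 1L < iv[1L] | anchors > iv[2L])
    }
    anchors <- anchors[ok]
  }
  starts <- c(starts, anchors)
  ends <- c(ends, anchors + rl - 1L)

  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]

  ground_truth <- integer(record$length)
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    ground_truth[idx] <- ground_truth[idx] + 1L
  }

  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", record$accession, record$length),
    sprintf("read%05d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
            seq_along(starts), record$accession, starts, rl,
            substring(record$sequence, starts, ends)))
  sam_path <- tempfile(fileext = ".sam")
  on.exit(unlink(sam_path))
  writeLines(sam, sam_path)
  dest <- sub("\\.bam$", "", bam_path)
  Rsamtools::asBam(sam_path, dest, overwrite = TRUE, indexDestination = TRUE)
  invisible(list(bam_path = paste0(dest, ".bam"),
                 ground_truth = ground_truth,
                 spans = data.frame(start = starts, end = ends)))
}

#' Build a complete fixture (flatfile + BAM) in one call
#'
#' @param spec a [fixture_spec()].
#' @param dir directory to write into.
#' @return list with `gbk_path`, `bam_path`, `record`, `regions`,
#'   `ground_truth`, `spans`.
#' @export
make_fixture <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genome <- make_genome(spec, file.path(dir, "genome.gb"))
  reads <- make_reads(spec, genome, file.path(dir, "reads.bam"))
  list(gbk_path = genome$path, bam_path = reads$bam_path,
       record = genome$record, regions = genome$regions,
       ground_truth = reads$ground_truth, spans = reads$spans)
}
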