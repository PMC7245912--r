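# Coverage engine: per-base depth from aligned-read spans via the start/end
# event sweep, fixed-size windows tiled per region (so no window crosses a
# region boundary and none is double-counted), and per-region averages.

#' Coverage configuration
#'
#' @param window_size window width in bp for the coverage histogram
#'   (default 250).
#' @param threshold coverage-depth threshold below which windows are
#'   flagged (default 0.5).
#' @param threshold_is_relative if `TRUE` (default) the threshold is a
#'   fraction of the genome-wide mean depth; otherwise it is an absolute
#'   depth.
#' @param log_transform if `TRUE`, display depths are `log10(x + 1)`
#'   transformed (flagging is always decided on untransformed depths).
#' @param flag_filter alignment-record categories excluded from counting;
#'   subset of `c("unmapped", "secondary", "supplementary", "qcfail",
#'   "duplicate")` (all excluded by default).
#' @return an object of class `coverage_config`.
#' @export
coverage_config <- function(window_size = 250L, threshold = 0.5,
                            threshold_is_relative = TRUE,
                            log_transform = FALSE,
                            flag_filter = c("unmapped", "secondary",
                                            "supplementary", "qcfail",
                                            "duplicate")) {
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L) {
    contract_error("window_size must be a positive integer")
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    contract_error("threshold must be positive")
  }
  bad <- setdiff(flag_filter,
                 c("unmapped", "secondary", "supplementary", "qcfail", "duplicate"))
  if (length(bad)) {
    contract_error(sprintf("unknown flag_filter categories: %s",
                           paste(bad, collapse = ", ")))
  }
  structure(list(window_size = window_size, threshold = threshold,
                 threshold_is_relative = isTRUE(threshold_is_relative),
                 log_transform = isTRUE(log_transform),
                 flag_filter = flag_filter),
            class = "coverage_config")
}

#' Per-base depth by the start/end event sweep
#'
#' Tracks the start and end positions of all aligned spans: a delta array
#' receives +1 at each span start and -1 just past each span end; the
#' cumulative sum yields the depth at every position. Identical to a naive
#' per-position pileup, in linear time.
#'
#' @param spans data.frame with integer columns `start`, `end`
#'   (1-based inclusive reference coordinates).
#' @param genome_length genome length in bp.
#' @return integer vector of per-base depths, 1-based index.
#' @export
sweep_depth <- function(spans, genome_length) {
  L <- as.integer(genome_length)
  if (is.null(spans) || nrow(spans) == 0L) return(integer(L))
  start <- as.integer(spans$start)
  end <- as.integer(spans$end)
  bad <- which(start < 1L | end > L | start > end)
  if (length(bad)) {
    validation_error(sprintf(
      "alignment span(s) outside [1, %d] or inverted: %s", L,
      paste(sprintf("%d..%d", start[bad[seq_len(min(3L, length(bad)))]],
                    end[bad[seq_len(min(3L, length(bad)))]]), collapse = ", ")))
  }
  delta <- tabulate(start, nbins = L) - tabulate(end + 1L, nbins = L + 1L)[seq_len(L)]
  cumsum(delta)
}

#' Read aligned spans from a sorted, indexed BAM file
#'
#' Yields one or more reference spans per retained alignment record:
#' deletions within a read are bridged (the read contributes a single
#' start/end span), while reference skips (intron-type N operations) split
#' the read into multiple spans. Records in excluded categories
#' (unmapped, secondary, supplementary, QC-fail, duplicate by default)
#' are skipped.
#'
#' @param path path to a coordinate-sorted BAM with an ancillary index.
#' @param record the parsed `plastome_record` the BAM was mapped against.
#' @param config a [coverage_config()].
#' @return data.frame with columns `start`, `end` (1-based inclusive).
#' @details The BAM reference is matched to the genome by name (reference
#'   name equal to the record accession); failing that, a single-reference
#'   BAM whose length equals the genome length is accepted. A reference
#'   length differing from the parsed genome length is a validation error.
#' @export
read_spans_from_bam <- function(path, record, config = coverage_config()) {
  stopifnot(inherits(record, "plastome_record"))
  if (!file.exists(path)) input_error(sprintf("BAM file not found: '%s'", path))
  idx_candidates <- c(paste0(path, ".bai"), sub("\\.bam$", ".bai", path))
  idx <- idx_candidates[file.exists(idx_candidates)]
  if (length(idx) == 0L) {
    input_error(sprintf(
      "no index found for '%s'; the BAM must be coordinate-sorted and indexed (e.g. 'samtools index %s')",
      path, path))
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1L]]$targets
  if (length(hdr) == 0L) input_error(sprintf("'%s' declares no reference sequences", path))
  if (record$accession %in% names(hdr)) {
    ref <- record$accession
  } else if (length(hdr) == 1L && unname(hdr[1L]) == record$length) {
    ref <- names(hdr)[1L]
  } else {
    input_error(sprintf(
      "no BAM reference matches the genome: expected name '%s' or a single reference of length %d (found: %s)",
      record$accession, record$length,
      paste(sprintf("%s:%d", names(hdr), hdr), collapse = ", ")))
  }
  if (unname(hdr[ref]) != record$length) {
    validation_error(sprintf(
      "BAM reference '%s' has length %d but the genome is %d bp",
      ref, hdr[ref], record$length))
  }
  drop <- function(cat) cat %in% config$flag_filter
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = if (drop("unmapped")) FALSE else NA,
    isSecondaryAlignment = if (drop("secondary")) FALSE else NA,
    isSupplementaryAlignment = if (drop("supplementary")) FALSE else NA,
    isNotPassingQualityControls = if (drop("qcfail")) FALSE else NA,
    isDuplicate = if (drop("duplicate")) FALSE else NA)
  which <- GenomicRanges::GRanges(ref, IRanges::IRanges(1L, record$length))
  bf <- Rsamtools::BamFile(path, index = idx[1L])
  gal <- GenomicAlignments::readGAlignments(
    bf, param = Rsamtools::ScanBamParam(flag = flag, which = which))
  # grglist() bridges D operations and splits at N gaps, i.e. one span per
  # reference-consuming alignment block in the sense used here
  blocks <- unlist(GenomicAlignments::grglist(gal), use.names = FALSE)
  data.frame(start = GenomicRanges::start(blocks),
             end = GenomicRanges::end(blocks))
}

#' Tile per-base depths into windows, per region
#'
#' Each region is tiled independently from its own start with windows of
#' exactly `window_size` bases plus, where needed, one shorter remainder
#' window per region, so that no window crosses a region boundary and the
#' windows jointly cover every position exactly once.
#'
#' @param per_base integer vector of per-base depths.
#' @param partition a `quadripartite_partition`.
#' @param window_size window width in bp.
#' @return data.frame of windows with columns `region_label`, `start`,
#'   `end`, `total` (summed depth), `mean_depth`, `display_depth`
#'   (initially equal to `mean_depth`), `flagged` (initially `NA`).
#' @export
windowize <- function(per_base, partition, window_size = 250L) {
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L) {
    contract_error("window_size must be >= 1")
  }
  if (length(per_base) != partition$genome_length) {
    contract_error("per_base length does not match the partition's genome length")
  }
  cs <- c(0, cumsum(as.numeric(per_base)))
  out <- lapply(seq_len(nrow(partition$regions)), function(i) {
    r <- partition$regions[i, ]
    starts <- seq.int(r$start, r$end, by = window_size)
    ends <- pmin(starts + window_size - 1L, r$end)
    total <- cs[ends + 1L] - cs[starts]
    data.frame(region_label = r$label, start = starts, end = ends,
               total = total, mean_depth = total / (ends - starts + 1L),
               stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, out)
  w$display_depth <- w$mean_depth
  w$flagged <- NA
  rownames(w) <- NULL
  w
}

#' Mean coverage depth per region
#'
#' Average over each region's own positions only (positions with zero
#' coverage included); every position contributes to exactly one region
#' label.
#'
#' @param per_base integer vector of per-base depths.
#' @param partition a `quadripartite_partition`.
#' @return named numeric vector of mean depths, one entry per region label.
#' @export
region_means <- function(per_base, partition) {
  if (length(per_base) != partition$genome_length) {
    contract_error("per_base length does not match the partition's genome length")
  }
  cs <- c(0, cumsum(as.numeric(per_base)))
  r <- partition$regions
  tot <- cs[r$end + 1L] - cs[r$start]
  len <- r$end - r$start + 1L
  labs <- unique(r$label)
  out <- tapply(tot, r$label, sum)[labs] / tapply(len, r$label, sum)[labs]
  stats::setNames(as.numeric(out), labs)
}

#' Flag low-coverage windows
#'
#' The effective cutoff is `threshold * genome_mean` when the threshold is
#' relative, else the threshold itself; a window is flagged iff its mean
#' depth is strictly below the cutoff (ties are displayed as normal).
#'
#' @param windows window data.frame from [windowize()].
#' @param genome_mean genome-wide mean depth over all positions.
#' @param config a [coverage_config()].
#' @return the window data.frame with `flagged` filled in; the numeric
#'   cutoff is attached as attribute `"cutoff"`.
#' @export
flag_windows <- function(windows, genome_mean, config = coverage_config()) {
  cutoff <- if (config$threshold_is_relative) {
    config$threshold * genome_mean
  } else {
    config$threshold
  }
  windows$flagged <- windows$mean_depth < cutoff
  attr(windows, "cutoff") <- cutoff
  windows
}

#' Log-transform window depths for display
#'
#' Sets `display_depth = log10(mean_depth + 1)`. Flagging is decided on
#' untransformed depths and is unaffected.
#'
#' @param windows window data.frame.
#' @return the window data.frame with transformed `display_depth`.
#' @export
log_transform_depths <- function(windows) {
  windows$display_depth <- log10(windows$mean_depth + 1)
  windows
}

#' Compute the full coverage track for a genome
#'
#' Convenience wrapper running [sweep_depth()], [windowize()],
#' [region_means()], [flag_windows()] and, when configured,
#' [log_transform_depths()].
#'
#' @param record a `plastome_record`.
#' @param partition a `quadripartite_partition`.
#' @param bam_path path to the sorted, indexed BAM (ignored when `spans`
#'   is supplied).
#' @param spans optional precomputed span data.frame (columns `start`,
#'   `end`), e.g. from a read simulator.
#' @param config a [coverage_config()].
#' @return an object of class `coverage_track`: a list with
#'   `genome_length`, `per_base`, `genome_mean`, `region_means` (named
#'   numeric), `windows` (flagged window data.frame) and `cutoff`.
#' @export
compute_coverage <- function(record, partition, bam_path = NULL, spans = NULL,
                             config = coverage_config()) {
  if (is.null(spans)) {
    if (is.null(bam_path)) contract_error("either bam_path or spans is required")
    spans <- read_spans_from_bam(bam_path, record, config)
  }
  per_base <- sweep_depth(spans, record$length)
  genome_mean <- sum(as.numeric(per_base)) / record$length
  windows <- windowize(per_base, partition, config$window_size)
  windows <- flag_windows(windows, genome_mean, config)
  if (config$log_transform) windows <- log_transform_depths(windows)
  structure(list(genome_length = record$length,
                 per_base = per_base,
                 genome_mean = genome_mean,
                 region_means = region_means(per_base, partition),
                 windows = windows,
                 cutoff = attr(windows, "cutoff")),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s bp, genome mean %.2fx, %d windows (%d flagged)\n",
              format(x$genome_length, big.mark = ","), x$genome_mean,
              nrow(x$windows), sum(x$windows$flagged, na.rm = TRUE)))
  invisible(x)
}

# -- pipeline exports ---------------------------------------------------------

#' Export the windowed coverage track as bedGraph
#'
#' Coordinates are converted to the 0-based half-open convention on
#' export.
#'
#' @param windows window data.frame.
#' @param ref_name reference (chromosome) name to print.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(windows, ref_name, path) {
  lines <- sprintf("%s\t%d\t%d\t%.6g", ref_name,
                   windows$start - 1L, windows$end, windows$mean_depth)
  writeLines(c("track type=bedGraph name=window_coverage", lines), path)
  invisible(path)
}

#' Export flagged (low-coverage) windows as BED
#'
#' @inheritParams write_bedgraph
#' @return `path`, invisibly.
#' @export
write_flagged_bed <- function(windows, ref_name, path) {
  w <- windows[which(windows$flagged), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\tlow_coverage\t%d", ref_name,
                   w$start - 1L, w$end, as.integer(round(w$mean_depth)))
  writeLines(lines, path)
  invisible(path)
}
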