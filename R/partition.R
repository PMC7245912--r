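# Quadripartite partition: locate the inverted-repeat annotations and derive
# the ordered LSC / IRb / SSC / IRa regions (or a single WHOLE region when
# the genome lacks IRs, as in Prototheca-type plastomes).

REGION_LABELS <- c("LSC", "IRb", "SSC", "IRa")

new_region <- function(label, start, end) {
  if (end < start) {
    validation_error(sprintf("region %s has end (%d) before start (%d)",
                             label, end, start))
  }
  list(label = label, start = as.integer(start), end = as.integer(end))
}

#' Inclusive length of a region in base pairs
#' @param region a region (list with `start`, `end`) or a data.frame row.
#' @return integer, `end - start + 1`.
#' @export
inclusive_length <- function(region) {
  as.integer(region$end - region$start + 1L)
}

#' Region size in the printed-table convention
#'
#' Returns `end - start`, the parenthetical size convention used in
#' published region tables for plastomes. Note this is one less than the
#' inclusive span length returned by [inclusive_length()]; all internal
#' arithmetic uses inclusive lengths, this accessor exists only to
#' reproduce the printed convention.
#'
#' @param region a region (list or data.frame row with `start`, `end`).
#' @return integer, `end - start`.
#' @export
table_region_size <- function(region) {
  as.integer(region$end - region$start)
}

#' Find inverted-repeat annotations in a plastome record
#'
#' Scans `repeat_region` features (and, as a fallback, `misc_feature`)
#' for any qualifier value matching -- case-insensitively, after
#' whitespace normalization -- `"IRa"`/`"inverted repeat A"` or
#' `"IRb"`/`"inverted repeat B"`.
#'
#' @param record a `plastome_record`.
#' @return a list with elements `ira` and `irb`, each either `NULL` or a
#'   region (list with `label`, `start`, `end`).
#' @details Two conflicting annotations (distinct spans) for the same IR
#'   label raise a validation error naming both spans. Finding zero or one
#'   IR is reported as an informational notice, not an error.
#' @export
find_ir_annotations <- function(record) {
  stopifnot(inherits(record, "plastome_record"))
  f <- record$features
  found <- list(ira = NULL, irb = NULL)
  for (kinds in list("repeat_region", "misc_feature")) {
    cand <- f[f$kind %in% kinds, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      vals <- c(cand$qualifiers[[i]], cand$name[i])
      norm <- tolower(gsub("\\s+", " ", trimws(vals)))
      label <- if (any(norm %in% c("ira", "inverted repeat a"))) "IRa"
               else if (any(norm %in% c("irb", "inverted repeat b"))) "IRb"
               else next
      slot <- tolower(label)
      reg <- new_region(label, cand$start[i], cand$end[i])
      prev <- found[[slot]]
      if (is.null(prev)) {
        found[[slot]] <- reg
      } else if (prev$start != reg$start || prev$end != reg$end) {
        validation_error(sprintf(
          "conflicting %s annotations: %d..%d and %d..%d",
          label, prev$start, prev$end, reg$start, reg$end))
      }
    }
    # fall back to misc_feature only when repeat_region yielded neither IR
    if (!is.null(found$ira) || !is.null(found$irb)) break
  }
  n <- sum(!vapply(found, is.null, logical(1L)))
  if (n < 2L) {
    pcv_inform(sprintf(
      "%d inverted-repeat annotation(s) found; genome will be treated as unpartitioned unless both IRs are present", n))
  }
  found
}

#' Derive the quadripartite partition from IR annotations
#'
#' When both IRs are annotated, the two single-copy regions are the gaps
#' between them: with IRb preceding IRa along the sequence,
#' `LSC = [1, IRb.start - 1]` and `SSC = [IRb.end + 1, IRa.start - 1]`.
#' With fewer than two IRs, a single `WHOLE` region spans the genome.
#'
#' @param record a `plastome_record`.
#' @param ira,irb regions as returned by [find_ir_annotations()], or `NULL`.
#' @return an object of class `quadripartite_partition`: a list with
#'   `regions` (data.frame with `label`, `start`, `end`) and
#'   `has_quadripartite` (logical).
#' @details IR annotations not flush with the sequence ends leave a
#'   trailing segment after IRa; because the genome is circular this
#'   segment adjoins the LSC and is carried as a second LSC-labelled row
#'   (with a warning). Overlapping IRs are a validation error. IRa
#'   annotated before IRb is honored as labelled, with a warning.
#' @export
derive_partition <- function(record, ira = NULL, irb = NULL) {
  stopifnot(inherits(record, "plastome_record"))
  L <- record$length
  if (is.null(ira) || is.null(irb)) {
    regions <- data.frame(label = "WHOLE", start = 1L, end = L,
                          stringsAsFactors = FALSE)
    return(new_partition(regions, has_quadripartite = FALSE, genome_length = L))
  }
  if (max(ira$start, irb$start) <= min(ira$end, irb$end)) {
    validation_error(sprintf(
      "IR annotations overlap: IRb %d..%d vs IRa %d..%d",
      irb$start, irb$end, ira$start, ira$end))
  }
  if (ira$start < irb$start) {
    pcv_warn("IRa is annotated before IRb in sequence order; labels are honored as annotated",
             "plastocov_ir_order_warning")
    first <- ira; second <- irb
  } else {
    first <- irb; second <- ira
  }
  if (first$start < 2L) {
    validation_error("no single-copy segment precedes the first IR; degenerate partition")
  }
  if (second$start <= first$end + 1L) {
    validation_error("no single-copy segment separates the two IRs; degenerate partition")
  }
  regions <- data.frame(
    label = c("LSC", first$label, "SSC", second$label),
    start = c(1L, first$start, first$end + 1L, second$start),
    end = c(first$start - 1L, first$end, second$start - 1L, second$end),
    stringsAsFactors = FALSE)
  if (second$end < L) {
    pcv_warn(sprintf(
      "IR annotations are not flush with the sequence end; trailing segment %d..%d is treated as part of the LSC (circularly contiguous)",
      second$end + 1L, L),
      "plastocov_partition_gap_warning")
    regions <- rbind(regions,
                     data.frame(label = "LSC", start = second$end + 1L, end = L,
                                stringsAsFactors = FALSE))
  }
  new_partition(regions, has_quadripartite = TRUE, genome_length = L)
}

new_partition <- function(regions, has_quadripartite, genome_length) {
  rownames(regions) <- NULL
  p <- structure(list(regions = regions,
                      has_quadripartite = has_quadripartite,
                      genome_length = as.integer(genome_length)),
                 class = "quadripartite_partition")
  validate_partition(p)
}

validate_partition <- function(p) {
  r <- p$regions
  if (any(r$end < r$start)) validation_error("partition contains an empty region")
  if (r$start[1L] != 1L || r$end[nrow(r)] != p$genome_length ||
      (nrow(r) > 1L && any(r$start[-1L] != r$end[-nrow(r)] + 1L))) {
    validation_error("partition regions must be contiguous and cover [1, genome length]")
  }
  if (p$has_quadripartite) {
    if (!setequal(unique(r$label), REGION_LABELS)) {
      validation_error("quadripartite partition must carry labels LSC, IRb, SSC, IRa")
    }
  } else if (!identical(r$label, "WHOLE")) {
    validation_error("unpartitioned genome must consist of a single WHOLE region")
  }
  p
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  cat(sprintf("<quadripartite_partition> %s, %s bp\n",
              if (x$has_quadripartite) "LSC/IRb/SSC/IRa" else "unpartitioned",
              format(x$genome_length, big.mark = ",")))
  print(x$regions)
  invisible(x)
}

#' Region label for each genome position
#'
#' @param partition a `quadripartite_partition`.
#' @param positions integer vector of 1-based genome positions.
#' @return character vector of region labels, one per position.
#' @export
region_of_position <- function(partition, positions) {
  r <- partition$regions
  if (any(positions < 1L | positions > partition$genome_length)) {
    contract_error("positions outside [1, genome length]")
  }
  idx <- findInterval(positions, r$start)
  r$label[idx]
}

#' Collect the gene features of a record
#'
#' Returns features of kind `gene`, deduplicated by (name, span) and
#' ordered by start coordinate. When the record has no `gene` features,
#' falls back to the union of `CDS`/`tRNA`/`rRNA` features (with a
#' warning), since some records annotate products only.
#'
#' @param record a `plastome_record`.
#' @return data.frame of feature rows (same columns as `record$features`).
#' @export
collect_genes <- function(record) {
  stopifnot(inherits(record, "plastome_record"))
  f <- record$features
  genes <- f[f$kind == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) {
    genes <- f[f$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
    if (nrow(genes) > 0L) {
      pcv_warn("no 'gene' features found; falling back to CDS/tRNA/rRNA features",
               "plastocov_gene_fallback_warning")
    } else {
      pcv_warn("record contains no gene-like features; gene layer will be empty",
               "plastocov_gene_fallback_warning")
    }
  }
  genes <- genes[!duplicated(genes[, c("name", "start", "end")]), , drop = FALSE]
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}
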