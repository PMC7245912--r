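# IR equality assessment: the two inverted repeats of a healthy plastome
# assembly are reverse complements of each other and carry mirrored gene
# complements. Equality is assessed directly (length, then sequence) and
# indirectly (gene number, names, lengths, positions); every inequality
# yields a structured warning, and matched gene pairs feed the synteny
# ribbons of the circular map.

IR_WARNING_CLASSES <- c(length = "ir_length", sequence = "ir_sequence",
                        complement = "ir_gene_complement",
                        gene_length = "ir_gene_length")

#' Extract the two IR sequences from the genome
#'
#' @param record a `plastome_record`.
#' @param partition a quadripartite `quadripartite_partition`.
#' @return list with uppercase character strings `irb` and `ira`.
#' @export
extract_ir_sequences <- function(record, partition) {
  if (!isTRUE(partition$has_quadripartite)) {
    contract_error("IR sequences can only be extracted from a quadripartite partition")
  }
  r <- partition$regions
  get <- function(lab) {
    row <- r[r$label == lab, ][1L, ]
    toupper(substr(record$sequence, row$start, row$end))
  }
  list(irb = get("IRb"), ira = get("IRa"))
}

#' Direct IR equality: length, then sequence
#'
#' Two-step comparison: lengths are compared first; only when they are
#' equal is sequence content compared. Sequence equality accepts either
#' direct identity or reverse-complement identity, since annotation
#' conventions differ in recorded orientation.
#'
#' @param irb,ira IR sequences as character strings.
#' @return list with logicals `sequences_equal`, `lengths_equal` and a
#'   `warnings` data.frame (columns `class`, `message`).
#' @export
compare_ir_sequences <- function(irb, ira) {
  if (!nzchar(irb) || !nzchar(ira)) contract_error("IR sequences must be non-empty")
  warnings <- empty_warnings()
  lengths_equal <- nchar(irb) == nchar(ira)
  if (!lengths_equal) {
    warnings <- rbind(warnings, warning_record(
      IR_WARNING_CLASSES[["length"]],
      sprintf("IR lengths differ: IRb is %d bp, IRa is %d bp",
              nchar(irb), nchar(ira))))
    sequences_equal <- FALSE
  } else {
    sequences_equal <- identical(irb, ira) || identical(irb, revcomp(ira))
    if (!sequences_equal) {
      warnings <- rbind(warnings, warning_record(
        IR_WARNING_CLASSES[["sequence"]],
        "IR sequences differ (neither identical nor reverse complements)"))
    }
  }
  list(sequences_equal = sequences_equal, lengths_equal = lengths_equal,
       warnings = warnings)
}

#' Per-IR gene tables
#'
#' @param units gene units from [split_genes_at_boundaries()] (each unit
#'   lies in exactly one region).
#' @param partition a `quadripartite_partition`.
#' @return list of two data.frames `irb` and `ira`, each with columns
#'   `name`, `start`, `end`, `length` (inclusive), ordered by start.
#' @export
ir_gene_tables <- function(units, partition) {
  if (!isTRUE(partition$has_quadripartite)) {
    contract_error("IR gene tables require a quadripartite partition")
  }
  side <- function(lab) {
    u <- units[units$region_label == lab, , drop = FALSE]
    u <- u[order(u$start), , drop = FALSE]
    data.frame(name = u$name, start = u$start, end = u$end,
               length = u$end - u$start + 1L,
               central = central_nucleotide(u$start, u$end),
               stringsAsFactors = FALSE)
  }
  list(irb = side("IRb"), ira = side("IRa"))
}

#' Match genes across the two IRs
#'
#' Genes are paired by identical name. Duplicate names within one IR are
#' paired by mirrored rank: because the IRs are reverse complements, the
#' k-th occurrence along IRb (5'->3') pairs with the k-th occurrence along
#' IRa counted 3'->5'. Leftover genes become unmatched entries and raise a
#' gene-complement warning; pairs whose members differ in inclusive length
#' raise a length-difference warning but remain paired.
#'
#' @param irb_table,ira_table tables from [ir_gene_tables()].
#' @return list with `matched_pairs` (data.frame: `name`, `b_start`,
#'   `b_end`, `b_length`, `b_central`, `a_start`, `a_end`, `a_length`,
#'   `a_central`), `unmatched` (data.frame with `side` column) and
#'   `warnings`.
#' @export
match_ir_genes <- function(irb_table, ira_table) {
  warnings <- empty_warnings()
  pairs <- list()
  unmatched <- list()
  for (nm in union(irb_table$name, ira_table$name)) {
    b <- irb_table[irb_table$name == nm, , drop = FALSE]       # 5'->3'
    a <- ira_table[ira_table$name == nm, , drop = FALSE]
    a <- a[rev(seq_len(nrow(a))), , drop = FALSE]              # 3'->5' (mirrored)
    k <- min(nrow(b), nrow(a))
    if (k > 0L) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        name = nm,
        b_start = b$start[seq_len(k)], b_end = b$end[seq_len(k)],
        b_length = b$length[seq_len(k)], b_central = b$central[seq_len(k)],
        a_start = a$start[seq_len(k)], a_end = a$end[seq_len(k)],
        a_length = a$length[seq_len(k)], a_central = a$central[seq_len(k)],
        stringsAsFactors = FALSE)
    }
    leftover <- function(tab, side) {
      if (nrow(tab) > k) {
        extra <- tab[(k + 1L):nrow(tab), , drop = FALSE]
        extra$side <- side
        unmatched[[length(unmatched) + 1L]] <<- extra
        for (j in seq_len(nrow(extra))) {
          warnings <<- rbind(warnings, warning_record(
            IR_WARNING_CLASSES[["complement"]],
            sprintf("gene '%s' (%d..%d) in %s has no counterpart in the other IR",
                    extra$name[j], extra$start[j], extra$end[j], side)))
        }
      }
    }
    leftover(b, "IRb")
    leftover(a, "IRa")
  }
  matched <- if (length(pairs)) do.call(rbind, pairs) else data.frame(
    name = character(), b_start = integer(), b_end = integer(),
    b_length = integer(), b_central = integer(), a_start = integer(),
    a_end = integer(), a_length = integer(), a_central = integer(),
    stringsAsFactors = FALSE)
  diff_len <- which(matched$b_length != matched$a_length)
  for (j in diff_len) {
    warnings <- rbind(warnings, warning_record(
      IR_WARNING_CLASSES[["gene_length"]],
      sprintf("paired gene '%s' differs in length between IRs: %d bp vs %d bp",
              matched$name[j], matched$b_length[j], matched$a_length[j])))
  }
  un <- if (length(unmatched)) do.call(rbind, unmatched) else {
    u <- irb_table[0, , drop = FALSE]; u$side <- character(); u
  }
  rownames(matched) <- rownames(un) <- NULL
  list(matched_pairs = matched, unmatched = un, warnings = warnings)
}

#' Ribbon endpoints and widths for matched IR gene pairs
#'
#' Connector ribbons originate and end at the central nucleotide of each
#' paired gene. Widths (in bp of arc) are proportional to each member's
#' inclusive length by default, or uniform.
#'
#' @param pairs `matched_pairs` data.frame from [match_ir_genes()].
#' @param mode `"proportional"` (default) or `"uniform"`.
#' @param uniform_width arc width in bp used in uniform mode.
#' @return data.frame with `name`, `b_pos`, `a_pos`, `b_width`, `a_width`.
#' @export
ribbon_endpoints <- function(pairs, mode = c("proportional", "uniform"),
                             uniform_width = 200L) {
  mode <- match.arg(mode)
  data.frame(
    name = pairs$name,
    b_pos = pairs$b_central, a_pos = pairs$a_central,
    b_width = if (mode == "proportional") pairs$b_length else rep(as.integer(uniform_width), nrow(pairs)),
    a_width = if (mode == "proportional") pairs$a_length else rep(as.integer(uniform_width), nrow(pairs)),
    stringsAsFactors = FALSE)
}

#' Full IR equality assessment
#'
#' Runs the direct (length, sequence) and indirect (gene complement,
#' synteny) comparisons and emits each warning on the condition channel in
#' addition to returning it structurally. Skipped entirely -- with an
#' informational notice, not a warning -- when the genome has no
#' quadripartite structure.
#'
#' @param record a `plastome_record`.
#' @param partition a `quadripartite_partition`.
#' @param units gene units from [split_genes_at_boundaries()].
#' @return an object of class `ir_comparison`: a list with
#'   `sequences_equal`, `lengths_equal`, `gene_count_equal`,
#'   `matched_pairs`, `unmatched`, `warnings`, `skipped`. When skipped,
#'   only `skipped = TRUE` is meaningful.
#' @export
compare_irs <- function(record, partition, units) {
  if (!isTRUE(partition$has_quadripartite)) {
    pcv_inform("no quadripartite structure: IR equality assessment and synteny visualization skipped")
    return(structure(list(skipped = TRUE, warnings = empty_warnings()),
                     class = "ir_comparison"))
  }
  seqs <- extract_ir_sequences(record, partition)
  direct <- compare_ir_sequences(seqs$irb, seqs$ira)
  tabs <- ir_gene_tables(units, partition)
  indirect <- match_ir_genes(tabs$irb, tabs$ira)
  warnings <- rbind(direct$warnings, indirect$warnings)
  for (i in seq_len(nrow(warnings))) {
    pcv_warn(warnings$message[i],
             paste0("plastocov_", warnings$class[i], "_warning"))
  }
  structure(list(
    skipped = FALSE,
    sequences_equal = direct$sequences_equal,
    lengths_equal = direct$lengths_equal,
    gene_count_equal = nrow(tabs$irb) == nrow(tabs$ira),
    ir_tables = tabs,
    matched_pairs = indirect$matched_pairs,
    unmatched = indirect$unmatched,
    warnings = warnings), class = "ir_comparison")
}

#' @export
print.ir_comparison <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat("<ir_comparison> skipped (no quadripartite structure)\n")
    return(invisible(x))
  }
  cat(sprintf("<ir_comparison> sequences %s, lengths %s, %d gene pair(s), %d unmatched, %d warning(s)\n",
              if (x$sequences_equal) "equal" else "UNEQUAL",
              if (x$lengths_equal) "equal" else "UNEQUAL",
              nrow(x$matched_pairs), nrow(x$unmatched), nrow(x$warnings)))
  invisible(x)
}

#' Write the two IR gene tables as TSV
#'
#' @param comparison an `ir_comparison` (not skipped).
#' @param path_irb,path_ira output file paths.
#' @return invisibly, a character vector of the two paths.
#' @export
write_ir_tables <- function(comparison, path_irb, path_ira) {
  if (isTRUE(comparison$skipped)) contract_error("comparison was skipped; no tables to write")
  utils::write.table(comparison$ir_tables$irb, path_irb, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(comparison$ir_tables$ira, path_ira, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(path_irb, path_ira))
}
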