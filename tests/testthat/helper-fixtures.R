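# Shared test helpers: an independent naive pileup oracle, a minimal
# flatfile text builder (independent of the package's writer, so parser
# tests are not self-referential), and a cached default fixture.

# brute-force per-position pileup; the oracle for the event-sweep algorithm
naive_pileup <- function(spans, L) {
  depth <- integer(L)
  for (i in seq_len(nrow(spans))) {
    idx <- spans$start[i]:spans$end[i]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

# format one feature-table line pair (header + qualifier lines)
feat_lines <- function(kind, loc, ...) {
  quals <- c(...)
  out <- sprintf("     %-15s %s", kind, loc)
  for (k in names(quals)) {
    out <- c(out, sprintf('                     /%s="%s"', k, quals[[k]]))
  }
  out
}

# write a flatfile by hand (NOT via write_genbank)
write_test_gb <- function(path, sequence, feature_lines = character(),
                          accession = "TST1", organism = "Testus plantus",
                          extra_records = 0L) {
  L <- nchar(sequence)
  seq_block <- character()
  for (p in seq(1L, L, by = 60L)) {
    chunk <- tolower(substr(sequence, p, min(p + 59L, L)))
    grp <- substring(chunk, seq(1, nchar(chunk), 10),
                     pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    seq_block <- c(seq_block, sprintf("%9d %s", p, paste(grp, collapse = " ")))
  }
  rec <- c(
    sprintf("LOCUS       %s             %d bp    DNA     circular PLN 01-JAN-2026",
            accession, L),
    sprintf("ACCESSION   %s", accession),
    sprintf("SOURCE      %s", organism),
    sprintf("  ORGANISM  %s", organism),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L),
    feature_lines,
    "ORIGIN",
    seq_block,
    "//")
  writeLines(rep(rec, times = 1L + extra_records), path)
  invisible(path)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# a plastome_record without going through file parsing
bare_record <- function(sequence, features = NULL, accession = "TST1",
                        organism = "Testus plantus") {
  if (is.null(features)) features <- plastocov:::empty_features()
  plastocov:::new_plastome_record(accession, organism, sequence, features)
}

# an unvalidated partition-shaped object for low-level extraction tests
raw_partition <- function(regions, has_quadripartite, genome_length) {
  structure(list(regions = regions, has_quadripartite = has_quadripartite,
                 genome_length = as.integer(genome_length)),
            class = "quadripartite_partition")
}

# all permutations of 1..n (n small); for exhaustive assignment oracles
combinat_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- combinat_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    unname(cbind(k, sub + (sub >= k)))
  }))
}

# cached default fixture: built once per test run
default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(suppressMessages(make_fixture(fixture_spec())))
    }
    cache
  }
})

# parse + partition a fixture, silencing expected notices
fixture_model <- function(fx) {
  suppressWarnings(suppressMessages({
    record <- parse_genbank(fx$gbk_path)
    irs <- find_ir_annotations(record)
    partition <- derive_partition(record, ira = irs$ira, irb = irs$irb)
    units <- split_genes_at_boundaries(collect_genes(record), partition)
    list(record = record, partition = partition, units = units)
  }))
}
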