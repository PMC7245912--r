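# GenBank flatfile model: a hand-written reader (and a minimal writer used
# by the fixture generator). Coordinates are kept 1-based inclusive, exactly
# as the annotation file shows them to the user; conversion to 0-based
# half-open happens only at the BAM-reading boundary and on BED export.

FEATURE_KINDS <- c("gene", "CDS", "tRNA", "rRNA", "repeat_region", "misc_feature")

#' Parse a GenBank flatfile into a plastome record
#'
#' Reads the first sequence record of a GenBank flatfile and returns a
#' validated in-memory model: accession, organism, sequence, and the feature
#' table. Compound locations (`join`/`complement`) are expanded into one
#' feature row per sub-span; rows originating from the same source feature
#' share a `group_id`, so multi-span genes (e.g. trans-spliced *rps12*) can
#' be re-associated downstream.
#'
#' @param path path to a GenBank flatfile containing at least one record
#'   with an `ORIGIN` sequence block.
#' @return an object of class `plastome_record`: a list with elements
#'   `accession`, `organism`, `length`, `sequence` (uppercase character
#'   string) and `features` (data.frame with columns `kind`, `name`,
#'   `start`, `end`, `strand`, `group_id`, `part`, and a list-column
#'   `qualifiers` of named character vectors).
#' @details Files with more than one record trigger a warning; only the
#'   first record is used. Origin-wrapping feature locations
#'   (`start > end`) are rejected. A genome length outside the 50--250 kb
#'   range typical of photoautotrophic land-plant plastomes produces a
#'   warning, never a failure.
#' @export
parse_genbank <- function(path) {
  if (length(path) != 1L || !is.character(path)) {
    contract_error("'path' must be a single file path")
  }
  if (!file.exists(path)) {
    input_error(sprintf("GenBank file not found: '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  terms <- grep("^//", lines)
  if (length(terms) == 0L) {
    recs <- list(lines)
  } else {
    starts <- c(1L, head(terms, -1L) + 1L)
    recs <- Map(function(s, e) lines[s:(e - 1L)], starts, terms)
    recs <- Filter(function(x) any(nzchar(trimws(x))), recs)
  }
  if (length(recs) == 0L) {
    validation_error(sprintf("no sequence record found in '%s'", path))
  }
  if (length(recs) > 1L) {
    pcv_warn(sprintf("'%s' contains %d records; only the first is used",
                     path, length(recs)),
             "plastocov_multi_record_warning")
  }
  record <- parse_gb_record(recs[[1L]], path)
  if (record$length < 50000L || record$length > 250000L) {
    pcv_warn(sprintf(
      "genome length %s bp is outside the preferred 50-250 kb plastome range; the map may be poorly scaled",
      format(record$length, big.mark = ",")),
      "plastocov_size_range_warning")
  }
  record
}

parse_gb_record <- function(lines, path) {
  locus_ln <- grep("^LOCUS", lines, value = TRUE)
  locus_name <- if (length(locus_ln)) strsplit(trimws(locus_ln[1L]), "\\s+")[[1L]][2L] else NA_character_
  acc_ln <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_ln)) strsplit(trimws(acc_ln[1L]), "\\s+")[[1L]][2L] else locus_name
  if (is.na(accession) || !nzchar(accession)) accession <- "UNKNOWN"
  org_ln <- grep("^ {2}ORGANISM", lines, value = TRUE)
  organism <- if (length(org_ln)) {
    trimws(sub("^ {2}ORGANISM\\s*", "", org_ln[1L]))
  } else {
    src_ln <- grep("^SOURCE", lines, value = TRUE)
    if (length(src_ln)) trimws(sub("^SOURCE\\s*", "", src_ln[1L])) else "Unknown organism"
  }

  origin_i <- grep("^ORIGIN", lines)
  sequence <- ""
  if (length(origin_i)) {
    seq_lines <- lines[seq(origin_i[1L] + 1L, length(lines))]
    sequence <- toupper(paste(gsub("[^A-Za-z]", "", seq_lines), collapse = ""))
  }
  if (!nzchar(sequence)) {
    validation_error(sprintf("record in '%s' has no ORIGIN sequence block", path))
  }
  glen <- nchar(sequence)

  feat_i <- grep("^FEATURES", lines)
  features <- empty_features()
  if (length(feat_i)) {
    stop_i <- if (length(origin_i)) origin_i[1L] else length(lines) + 1L
    base_i <- grep("^BASE COUNT", lines)
    if (length(base_i)) stop_i <- min(stop_i, base_i[1L])
    if (stop_i - 1L > feat_i[1L]) {
      features <- parse_feature_table(lines[(feat_i[1L] + 1L):(stop_i - 1L)], glen)
    }
  }

  new_plastome_record(accession, organism, sequence, features)
}

new_plastome_record <- function(accession, organism, sequence, features) {
  record <- structure(
    list(accession = accession, organism = organism,
         length = nchar(sequence), sequence = sequence, features = features),
    class = "plastome_record")
  validate_plastome_record(record)
}

validate_plastome_record <- function(record) {
  if (record$length < 1L) validation_error("genome length must be positive")
  if (record$length != nchar(record$sequence)) {
    validation_error("record length does not equal sequence length")
  }
  f <- record$features
  if (nrow(f)) {
    bad <- f$start < 1L | f$end > record$length
    if (any(bad)) {
      validation_error(sprintf(
        "feature coordinates outside [1, %d]: %s",
        record$length,
        paste(sprintf("%s %d..%d", f$name[bad], f$start[bad], f$end[bad]),
              collapse = ", ")))
    }
  }
  record
}

empty_features <- function() {
  data.frame(kind = character(), name = character(),
             start = integer(), end = integer(), strand = character(),
             group_id = integer(), part = integer(),
             qualifiers = I(list()), stringsAsFactors = FALSE)
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s (%s)\n", x$accession, x$organism))
  cat(sprintf("  length: %s bp; features: %d\n",
              format(x$length, big.mark = ","), nrow(x$features)))
  invisible(x)
}

# -- feature table ------------------------------------------------------------

parse_feature_table <- function(lines, genome_length) {
  # A feature header has its key in columns 6-20; continuation lines are
  # blank through column 21. Everything else (including the source line's
  # qualifiers) is continuation text of the current feature.
  feats <- list()
  cur <- NULL
  for (ln in lines) {
    if (grepl("^ {5}\\S", ln)) {
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      key <- trimws(substr(ln, 6L, 20L))
      rest <- trimws(substr(ln, 21L, nchar(ln)))
      cur <- list(key = key, text = rest)
    } else if (!is.null(cur) && nzchar(trimws(ln))) {
      cur$text <- c(cur$text, trimws(ln))
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur

  rows <- list()
  gid <- 0L
  for (ft in feats) {
    if (identical(ft$key, "source")) next
    gid <- gid + 1L
    parsed <- parse_feature_text(ft$text)
    spans <- parse_location(parsed$location)
    if (any(spans$start > spans$end)) {
      validation_error(sprintf(
        "origin-wrapping feature location '%s' (%s) is not supported; linearize the annotation first",
        parsed$location, ft$key))
    }
    if (any(spans$start < 1L) || any(spans$end > genome_length)) {
      validation_error(sprintf(
        "feature location '%s' (%s) outside [1, %d]",
        parsed$location, ft$key, genome_length))
    }
    nm <- feature_name(ft$key, parsed$qualifiers)
    n <- nrow(spans)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = rep(ft$key, n), name = rep(nm, n),
      start = spans$start, end = spans$end, strand = spans$strand,
      group_id = rep(gid, n), part = seq_len(n) - 1L,
      qualifiers = I(rep(list(parsed$qualifiers), n)),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_features())
  do.call(rbind, rows)
}

parse_feature_text <- function(text_lines) {
  # Location lines come first; the first line starting with '/' begins the
  # qualifier block. Multi-line qualifier values are joined with a space.
  qual_start <- which(startsWith(text_lines, "/"))
  if (length(qual_start)) {
    loc <- paste(text_lines[seq_len(qual_start[1L] - 1L)], collapse = "")
    qlines <- text_lines[qual_start[1L]:length(text_lines)]
  } else {
    loc <- paste(text_lines, collapse = "")
    qlines <- character()
  }
  quals <- character()
  key <- NULL; val <- NULL
  flush <- function() {
    if (!is.null(key)) {
      v <- gsub("\\s+", " ", trimws(val))
      v <- gsub('^"|"$', "", v)
      quals[key] <<- v
    }
  }
  for (q in qlines) {
    if (startsWith(q, "/")) {
      flush()
      m <- regmatches(q, regexec("^/([^=]+)(=(.*))?$", q))[[1L]]
      key <- m[2L]
      val <- if (length(m) >= 4L) m[4L] else ""
    } else {
      val <- paste(val, q)
    }
  }
  flush()
  list(location = loc, qualifiers = quals)
}

feature_name <- function(kind, qualifiers) {
  for (k in c("gene", "label", "standard_name", "rpt_name", "note", "product")) {
    if (!is.null(qualifiers[k]) && !is.na(qualifiers[k]) && nzchar(qualifiers[k])) {
      return(unname(qualifiers[k]))
    }
  }
  kind
}

# -- location expressions -----------------------------------------------------

parse_location <- function(loc) {
  s <- gsub("[<>\\s]", "", loc, perl = TRUE)
  if (!nzchar(s)) validation_error("empty feature location")
  df <- parse_loc_expr(s, "+")
  # sub-spans are kept in genome order regardless of join/complement nesting
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

parse_loc_expr <- function(s, strand) {
  if (startsWith(s, "complement(")) {
    inner <- substr(s, nchar("complement(") + 1L, nchar(s) - 1L)
    df <- parse_loc_expr(inner, if (strand == "+") "-" else "+")
    # complement reverses sub-span order; restore genome order later by sort
    return(df[rev(seq_len(nrow(df))), , drop = FALSE])
  }
  if (startsWith(s, "join(") || startsWith(s, "order(")) {
    op <- if (startsWith(s, "join(")) "join(" else "order("
    inner <- substr(s, nchar(op) + 1L, nchar(s) - 1L)
    parts <- split_top_commas(inner)
    return(do.call(rbind, lapply(parts, parse_loc_expr, strand = strand)))
  }
  m <- regmatches(s, regexec("^(\\d+)(\\.\\.|\\^)?(\\d+)?$", s))[[1L]]
  if (length(m) == 0L) {
    validation_error(sprintf("cannot parse feature location '%s'", s))
  }
  start <- as.integer(m[2L])
  end <- if (nzchar(m[4L])) as.integer(m[4L]) else start
  data.frame(start = start, end = end, strand = strand, stringsAsFactors = FALSE)
}

split_top_commas <- function(s) {
  depth <- 0L
  cut <- integer()
  chars <- strsplit(s, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == "," && depth == 0L) cut <- c(cut, i)
  }
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  mapply(function(a, b) paste(chars[a:b], collapse = ""), starts, ends)
}

# -- minimal writer (fixture support) -----------------------------------------

#' Write a plastome record as a minimal GenBank flatfile
#'
#' Emits a single-record flatfile sufficient for round-tripping through
#' [parse_genbank()]: LOCUS/ACCESSION/ORGANISM headers, the feature table
#' (one location per feature row; minus-strand rows written as
#' `complement(a..b)`), and the ORIGIN sequence block. Used by the fixture
#' generator; not a general-purpose GenBank emitter.
#'
#' @param record a `plastome_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "plastome_record"))
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     circular PLN 01-JAN-2026",
            record$accession, record$length),
    sprintf("DEFINITION  %s plastid, complete genome.", record$organism),
    sprintf("ACCESSION   %s", record$accession),
    sprintf("SOURCE      %s", record$organism),
    sprintf("  ORGANISM  %s", record$organism),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", record$length),
    sprintf('                     /organism="%s"', record$organism))
  f <- record$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     %-15s %s", f$kind[i], loc))
    q <- f$qualifiers[[i]]
    for (k in names(q)) {
      out <- c(out, sprintf('                     /%s="%s"', k, q[[k]]))
    }
  }
  out <- c(out, "ORIGIN")
  seq_lc <- tolower(record$sequence)
  pos <- seq(1L, record$length, by = 60L)
  for (p in pos) {
    chunk <- substr(seq_lc, p, min(p + 59L, record$length))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(groups, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
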