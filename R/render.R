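# Circular renderer: a four-layer quadripartite plastome map.
# Layer builders produce plain data descriptions; map_geometry() turns them
# into drawing primitives on a fixed 1000x1000 canvas; one backend
# serializes the primitives as deterministic SVG (the structural test
# surface), another draws them on a grDevices device (PDF default, PNG).

CANVAS <- 1000
CX <- 500
CY <- 500
RAD <- 380

# radial bands, as fractions of RAD (outermost -> innermost layer)
R_TICK_IN <- 1.00
R_TICK_OUT <- 1.04
R_TICK_LAB <- 1.10
R_REGION_OUT <- 1.00
R_REGION_IN <- 0.93
R_GENE <- 0.85
R_BAR_OUT <- 0.80
R_BAR_IN <- 0.52
R_RIBBON <- 0.48

#' Map a genome position to an angle on the circle
#'
#' Position 1 maps to the top of the circle (12 o'clock); angles increase
#' clockwise, linearly in genomic distance, completing a full turn over
#' the genome length. All layers share this single mapping.
#'
#' @param position 1-based genome position(s).
#' @param genome_length genome length in bp.
#' @return angle(s) in radians, clockwise from the top.
#' @export
position_to_angle <- function(position, genome_length) {
  if (any(position < 1 | position > genome_length)) {
    contract_error(sprintf("position outside [1, %d]", genome_length))
  }
  pos_angle(position, genome_length)
}

# unchecked variant; also accepts fractional and boundary (L+1) positions
pos_angle <- function(position, genome_length) {
  2 * pi * (position - 1) / genome_length
}

pt_x <- function(r, a) CX + r * sin(a)
pt_y <- function(r, a) CY - r * cos(a)

# points along an arc at radius r between genome positions p0..p1
# (p1 may be end+1 to close a window exactly); max 2 degrees per step
arc_xy <- function(r, p0, p1, genome_length) {
  a0 <- pos_angle(p0, genome_length)
  a1 <- pos_angle(p1, genome_length)
  n <- max(2L, ceiling(abs(a1 - a0) / (2 * pi / 180)) + 1L)
  a <- seq(a0, a1, length.out = n)
  list(x = pt_x(r, a), y = pt_y(r, a))
}

region_palette <- function() {
  c(LSC = "#4f81bd", IRb = "#8064a2", SSC = "#c0504d", IRa = "#9bbb59",
    WHOLE = "#b8b8b8")
}

# -- layer builders -----------------------------------------------------------

#' Outermost layer: decile tick marks and colored region arcs
#'
#' Ten length-labelled tick marks at each decile of the genome length,
#' plus one colored arc per partition region with its label. A genome
#' without quadripartite structure gets a single homogeneous arc and no
#' region labels.
#'
#' @param partition a `quadripartite_partition`.
#' @param genome_length genome length in bp.
#' @return a layer description: list with data.frames `ticks`
#'   (`position`, `label`) and `regions` (`label`, `start`, `end`,
#'   `color`, `show_label`).
#' @export
layer_ticks_and_regions <- function(partition, genome_length) {
  k <- 1:10
  pos <- pmin(round(k * genome_length / 10), genome_length)
  ticks <- data.frame(position = as.integer(pos),
                      label = sprintf("%.1f kb", pos / 1000))
  pal <- region_palette()
  regions <- partition$regions
  regions$color <- unname(pal[regions$label])
  regions$show_label <- partition$has_quadripartite
  structure(list(ticks = ticks, regions = regions),
            class = c("map_layer_ticks_regions", "map_layer"))
}

#' Gene-label layer
#'
#' One radial label anchor per gene unit at its central nucleotide.
#' Duplicate adjacent labels of the same origin (parts of one split gene)
#' within a configurable angular distance are suppressed, keeping the
#' first.
#'
#' @param units gene units from [split_genes_at_boundaries()].
#' @param genome_length genome length in bp.
#' @param dedupe_arc angular distance as a fraction of the full circle
#'   below which same-origin labels collapse (default 0.01).
#' @return a layer description: data.frame with `name`, `position`.
#' @export
layer_gene_labels <- function(units, genome_length, dedupe_arc = 0.01) {
  if (nrow(units) == 0L) {
    return(structure(list(labels = data.frame(name = character(),
                                              position = integer())),
                     class = c("map_layer_genes", "map_layer")))
  }
  u <- units[order(units$origin_id, units$central), , drop = FALSE]
  keep <- rep(TRUE, nrow(u))
  min_sep <- dedupe_arc * genome_length
  last_pos <- -Inf; last_origin <- NA
  for (i in seq_len(nrow(u))) {
    if (!is.na(last_origin) && u$origin_id[i] == last_origin &&
        (u$central[i] - last_pos) < min_sep) {
      keep[i] <- FALSE
    } else {
      last_pos <- u$central[i]
    }
    last_origin <- u$origin_id[i]
  }
  labels <- data.frame(name = u$name[keep], position = u$central[keep])
  labels <- labels[order(labels$position), , drop = FALSE]
  rownames(labels) <- NULL
  structure(list(labels = labels),
            class = c("map_layer_genes", "map_layer"))
}

#' Coverage histogram layer
#'
#' One radial bar per window spanning the window's angular extent, with
#' height proportional to the (possibly log-transformed) display depth;
#' bars below the threshold are red, others black. Per region, a
#' constant-radius yellow arc marks the region's mean depth, broken over
#' maximal runs of zero-coverage windows ("missing in areas without
#' coverage").
#'
#' @param windows flagged window data.frame (from [flag_windows()]).
#' @param region_mean_depths named numeric vector from [region_means()].
#' @param config a [coverage_config()].
#' @return a layer description: list with `bars`, `mean_arcs`,
#'   `max_display`.
#' @export
layer_coverage_histogram <- function(windows, region_mean_depths,
                                     config = coverage_config()) {
  bars <- windows
  bars$color <- ifelse(bars$flagged, "#d62728", "#000000")
  disp_mean <- if (config$log_transform) log10(region_mean_depths + 1) else region_mean_depths
  arcs <- list()
  n <- nrow(windows)
  covered <- windows$total > 0
  run_start <- NULL
  for (i in seq_len(n)) {
    new_run <- covered[i] &&
      (is.null(run_start) || i == 1L ||
       !covered[i - 1L] || windows$region_label[i] != windows$region_label[i - 1L])
    if (new_run) run_start <- i
    run_ends <- covered[i] &&
      (i == n || !covered[i + 1L] || windows$region_label[i + 1L] != windows$region_label[i])
    if (run_ends) {
      lab <- windows$region_label[i]
      arcs[[length(arcs) + 1L]] <- data.frame(
        label = lab, start = windows$start[run_start], end = windows$end[i],
        depth = unname(disp_mean[lab]), stringsAsFactors = FALSE)
    }
  }
  mean_arcs <- if (length(arcs)) do.call(rbind, arcs) else
    data.frame(label = character(), start = integer(), end = integer(),
               depth = numeric())
  max_display <- max(c(bars$display_depth, mean_arcs$depth, 1e-9))
  structure(list(bars = bars, mean_arcs = mean_arcs, max_display = max_display),
            class = c("map_layer_coverage", "map_layer"))
}

#' Synteny-ribbon layer
#'
#' One chord ribbon per matched IR gene pair, between the central
#' nucleotides of the two members, with widths from [ribbon_endpoints()].
#' The layer is omitted entirely (returns `NULL`) when the genome is not
#' quadripartite.
#'
#' @param ribbons data.frame from [ribbon_endpoints()], or `NULL`.
#' @return a layer description or `NULL`.
#' @export
layer_synteny_ribbons <- function(ribbons) {
  if (is.null(ribbons)) return(NULL)
  structure(list(ribbons = ribbons),
            class = c("map_layer_ribbons", "map_layer"))
}

# -- plot spec ----------------------------------------------------------------

#' Assemble the full plot specification
#'
#' @param record a `plastome_record` (the organism name becomes the
#'   figure title).
#' @param partition a `quadripartite_partition`.
#' @param track a `coverage_track`.
#' @param units gene units from [split_genes_at_boundaries()].
#' @param comparison an `ir_comparison` (may be skipped).
#' @param config a [coverage_config()].
#' @param ribbon_mode `"proportional"`, `"uniform"`, or `"none"`.
#' @param text_scale size of all text elements relative to the maximum
#'   font size, in (0, 1]; default 0.5.
#' @param output_path output file path.
#' @param format `"pdf"`, `"svg"`, or `"png"`; default inferred from the
#'   output path extension, falling back to PDF.
#' @return an object of class `plot_spec`.
#' @export
build_plot_spec <- function(record, partition, track, units, comparison,
                            config = coverage_config(),
                            ribbon_mode = c("proportional", "uniform", "none"),
                            text_scale = 0.5,
                            output_path = "plastocov_output.pdf",
                            format = NULL) {
  ribbon_mode <- match.arg(ribbon_mode)
  if (!is.numeric(text_scale) || text_scale <= 0 || text_scale > 1) {
    contract_error("text_scale must be in (0, 1]")
  }
  ribbons <- NULL
  if (partition$has_quadripartite && ribbon_mode != "none" &&
      !isTRUE(comparison$skipped) && nrow(comparison$matched_pairs) > 0L) {
    ribbons <- ribbon_endpoints(comparison$matched_pairs, mode = ribbon_mode)
  }
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(output_path))
    format <- if (ext %in% c("svg", "png", "pdf")) ext else "pdf"
  }
  legend <- map_legend(track, partition, config)
  structure(list(
    title = record$organism,
    genome_length = record$length,
    layers = list(
      ticks_regions = layer_ticks_and_regions(partition, record$length),
      genes = layer_gene_labels(units, record$length),
      coverage = layer_coverage_histogram(track$windows, track$region_means, config),
      ribbons = layer_synteny_ribbons(ribbons)),
    legend = legend,
    text_scale = text_scale,
    output_path = output_path,
    format = format), class = "plot_spec")
}

map_legend <- function(track, partition, config) {
  lines <- if (config$threshold_is_relative) {
    sprintf("Low-coverage threshold: %.2fx (%.0f%% of genome-wide mean)",
            track$cutoff, 100 * config$threshold)
  } else {
    sprintf("Low-coverage threshold: %.2fx (absolute)", track$cutoff)
  }
  if (partition$has_quadripartite) {
    lines <- c(lines, sprintf("Mean depth %s: %.1fx",
                              names(track$region_means), track$region_means))
  } else {
    lines <- c(lines, sprintf("Mean depth (genome-wide): %.1fx", track$genome_mean))
  }
  lines
}

# -- geometry -----------------------------------------------------------------

prim_polygon <- function(class, x, y, fill, stroke = "none",
                         opacity = NULL, attrs = NULL) {
  list(type = "polygon", class = class, x = x, y = y, fill = fill,
       stroke = stroke, opacity = opacity, attrs = attrs)
}
prim_polyline <- function(class, x, y, stroke, width = 1.5) {
  list(type = "polyline", class = class, x = x, y = y, stroke = stroke,
       width = width)
}
prim_line <- function(class, x1, y1, x2, y2, stroke = "#000000", width = 1) {
  list(type = "line", class = class, x1 = x1, y1 = y1, x2 = x2, y2 = y2,
       stroke = stroke, width = width)
}
prim_text <- function(class, x, y, text, size, rot = 0, anchor = "middle",
                      fill = "#000000") {
  list(type = "text", class = class, x = x, y = y, text = text, size = size,
       rot = rot, anchor = anchor, fill = fill)
}

# Convert a plot spec to a flat list of drawing primitives.
map_geometry <- function(spec) {
  L <- spec$genome_length
  s <- spec$text_scale / 0.5   # 1.0 at the default text scale
  prims <- list()
  add <- function(p) prims[[length(prims) + 1L]] <<- p

  add(prim_text("title", CX, 42, spec$title, size = 20 * s))

  # layer 1: region arcs + ticks
  tr <- spec$layers$ticks_regions
  for (i in seq_len(nrow(tr$regions))) {
    r <- tr$regions[i, ]
    outer <- arc_xy(RAD * R_REGION_OUT, r$start, r$end + 1, L)
    inner <- arc_xy(RAD * R_REGION_IN, r$end + 1, r$start, L)
    add(prim_polygon("region-arc", c(outer$x, inner$x), c(outer$y, inner$y),
                     fill = r$color,
                     attrs = c("data-label" = r$label)))
    if (isTRUE(r$show_label)) {
      mid <- (r$start + r$end) / 2
      a <- pos_angle(mid, L)
      add(prim_text("region-label", pt_x(RAD * 0.965, a), pt_y(RAD * 0.965, a),
                    r$label, size = 11 * s, fill = "#ffffff"))
    }
  }
  for (i in seq_len(nrow(tr$ticks))) {
    tk <- tr$ticks[i, ]
    a <- pos_angle(tk$position, L)
    add(prim_line("tick",
                  pt_x(RAD * R_TICK_IN, a), pt_y(RAD * R_TICK_IN, a),
                  pt_x(RAD * R_TICK_OUT, a), pt_y(RAD * R_TICK_OUT, a)))
    add(prim_text("tick-label", pt_x(RAD * R_TICK_LAB, a),
                  pt_y(RAD * R_TICK_LAB, a), tk$label, size = 9 * s))
  }

  # layer 2: gene labels, radial orientation
  gl <- spec$layers$genes$labels
  for (i in seq_len(nrow(gl))) {
    a <- pos_angle(gl$position[i], L)
    deg <- a * 180 / pi
    flip <- deg > 90 && deg < 270
    add(prim_text("gene-label",
                  pt_x(RAD * R_GENE, a), pt_y(RAD * R_GENE, a),
                  gl$name[i], size = 8 * s,
                  rot = if (flip) deg else deg - 180,
                  anchor = if (flip) "end" else "start"))
  }

  # layer 3: coverage histogram + per-region mean arcs
  cov <- spec$layers$coverage
  band <- RAD * (R_BAR_OUT - R_BAR_IN)
  r0 <- RAD * R_BAR_IN
  for (i in seq_len(nrow(cov$bars))) {
    w <- cov$bars[i, ]
    h <- band * w$display_depth / cov$max_display
    outer <- arc_xy(r0 + h, w$start, w$end + 1, L)
    inner <- arc_xy(r0, w$end + 1, w$start, L)
    add(prim_polygon("cov-bar", c(outer$x, inner$x), c(outer$y, inner$y),
                     fill = w$color,
                     attrs = c("data-start" = w$start, "data-end" = w$end,
                               "data-flagged" = tolower(as.character(w$flagged)))))
  }
  for (i in seq_len(nrow(cov$mean_arcs))) {
    m <- cov$mean_arcs[i, ]
    r <- r0 + band * m$depth / cov$max_display
    xy <- arc_xy(r, m$start, m$end + 1, L)
    add(prim_polyline("mean-arc", xy$x, xy$y, stroke = "#ffcc00", width = 2))
  }

  # layer 4: synteny ribbons
  rb <- spec$layers$ribbons
  if (!is.null(rb)) {
    for (i in seq_len(nrow(rb$ribbons))) {
      p <- rb$ribbons[i, ]
      b1 <- p$b_pos - p$b_width / 2; b2 <- p$b_pos + p$b_width / 2
      a1 <- p$a_pos - p$a_width / 2; a2 <- p$a_pos + p$a_width / 2
      arc_b <- arc_xy(RAD * R_RIBBON, b1, b2, L)
      arc_a <- arc_xy(RAD * R_RIBBON, a1, a2, L)
      bez1 <- bezier_xy(RAD * R_RIBBON, b2, a1, L)
      bez2 <- bezier_xy(RAD * R_RIBBON, a2, b1, L)
      add(prim_polygon("ribbon",
                       c(arc_b$x, bez1$x, arc_a$x, bez2$x),
                       c(arc_b$y, bez1$y, arc_a$y, bez2$y),
                       fill = "#1f77b4", opacity = 0.55,
                       attrs = c("data-name" = p$name)))
    }
  }

  # legend, lower left
  for (i in seq_along(spec$legend)) {
    add(prim_text("legend", 28, 900 + 16 * s * (i - 1), spec$legend[i],
                  size = 10 * s, anchor = "start"))
  }
  prims
}

# quadratic bezier from position p0 to p1 (both on radius r), pulled
# toward the circle center; sampled as a polyline
bezier_xy <- function(r, p0, p1, genome_length) {
  a0 <- pos_angle(p0, genome_length)
  a1 <- pos_angle(p1, genome_length)
  x0 <- pt_x(r, a0); y0 <- pt_y(r, a0)
  x1 <- pt_x(r, a1); y1 <- pt_y(r, a1)
  t <- seq(0, 1, length.out = 24)
  list(x = (1 - t)^2 * x0 + 2 * (1 - t) * t * CX + t^2 * x1,
       y = (1 - t)^2 * y0 + 2 * (1 - t) * t * CY + t^2 * y1)
}

# -- backends -----------------------------------------------------------------

num <- function(x) sprintf("%.2f", x)

svg_serialize <- function(prims) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  attr_str <- function(attrs) {
    if (is.null(attrs)) return("")
    paste0(" ", paste(sprintf('%s="%s"', names(attrs), esc(as.character(attrs))),
                      collapse = " "))
  }
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d" font-family="Helvetica, Arial, sans-serif">',
            CANVAS, CANVAS, CANVAS, CANVAS),
    sprintf('<rect class="bg" x="0" y="0" width="%d" height="%d" fill="#ffffff"/>',
            CANVAS, CANVAS))
  for (p in prims) {
    out <- c(out, switch(
      p$type,
      polygon = sprintf(
        '<polygon class="%s" points="%s" fill="%s" stroke="%s"%s%s/>',
        p$class,
        paste(sprintf("%s,%s", num(p$x), num(p$y)), collapse = " "),
        p$fill, p$stroke,
        if (is.null(p$opacity)) "" else sprintf(' fill-opacity="%s"', num(p$opacity)),
        attr_str(p$attrs)),
      polyline = sprintf(
        '<polyline class="%s" points="%s" fill="none" stroke="%s" stroke-width="%s"/>',
        p$class,
        paste(sprintf("%s,%s", num(p$x), num(p$y)), collapse = " "),
        p$stroke, num(p$width)),
      line = sprintf(
        '<line class="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
        p$class, num(p$x1), num(p$y1), num(p$x2), num(p$y2),
        p$stroke, num(p$width)),
      text = sprintf(
        '<text class="%s" x="%s" y="%s" font-size="%s" text-anchor="%s" fill="%s"%s>%s</text>',
        p$class, num(p$x), num(p$y), num(p$size), p$anchor, p$fill,
        if (p$rot != 0) sprintf(' transform="rotate(%s %s %s)"',
                                num(p$rot), num(p$x), num(p$y)) else "",
        esc(p$text))))
  }
  c(out, "</svg>")
}

draw_prims <- function(prims) {
  op <- graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  on.exit(graphics::par(op))
  graphics::plot.new()
  # y axis flipped so primitive coordinates match the SVG convention
  graphics::plot.window(xlim = c(0, CANVAS), ylim = c(CANVAS, 0), asp = 1)
  for (p in prims) {
    switch(p$type,
      polygon = graphics::polygon(p$x, p$y,
        col = if (is.null(p$opacity)) p$fill else grDevices::adjustcolor(p$fill, alpha.f = p$opacity),
        border = if (identical(p$stroke, "none")) NA else p$stroke),
      polyline = graphics::lines(p$x, p$y, col = p$stroke, lwd = p$width),
      line = graphics::segments(p$x1, p$y1, p$x2, p$y2, col = p$stroke,
                                lwd = p$width),
      text = graphics::text(p$x, p$y, labels = p$text, col = p$fill,
        cex = p$size / 12, srt = -p$rot,
        adj = switch(p$anchor, start = c(0, 0.5), end = c(1, 0.5), c(0.5, 0.5))))
  }
}

#' Render the assembled map and write it to file
#'
#' Writes the multi-layer circular map -- title, tick/region layer, gene
#' labels, coverage histogram, synteny ribbons, and legend -- as a vector
#' file. SVG output is byte-deterministic for identical inputs; PDF (the
#' default) and PNG are drawn with base graphics from the same geometry.
#'
#' @param spec a `plot_spec` from [build_plot_spec()].
#' @return the output path, invisibly.
#' @export
compose_and_write <- function(spec) {
  stopifnot(inherits(spec, "plot_spec"))
  prims <- map_geometry(spec)
  path <- spec$output_path
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    pcv_stop(sprintf("output directory does not exist: '%s'", dir),
             "plastocov_io_error")
  }
  if (spec$format == "svg") {
    ok <- tryCatch({ writeLines(svg_serialize(prims), path); TRUE },
                   error = function(e) FALSE)
    if (!ok) pcv_stop(sprintf("cannot write '%s'", path), "plastocov_io_error")
  } else if (spec$format == "pdf") {
    grDevices::pdf(path, width = 10, height = 10, useDingbats = FALSE)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw_prims(prims)
  } else if (spec$format == "png") {
    grDevices::png(path, width = CANVAS, height = CANVAS,
                   type = if (capabilities("cairo")) "cairo" else getOption("bitmapType"))
    on.exit(grDevices::dev.off(), add = TRUE)
    draw_prims(prims)
  } else {
    contract_error(sprintf("unsupported output format '%s'", spec$format))
  }
  invisible(path)
}
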