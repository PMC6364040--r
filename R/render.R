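# Rendering: a deterministic categorical palette, a canonical textual plot
# specification (the reproducibility surface: byte-identical across runs for
# identical inputs), and the actual figure drawing to PDF/PNG/SVG. The
# renderer draws exactly the primitives listed in the plot spec.

# Curated categorical palette for up to 12 ancestries; beyond that, colors
# come from a deterministic evenly spaced hue rotation.
.base_palette <- c(
  "#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00", "#FFD92F",
  "#A65628", "#F781BF", "#66C2A5", "#1B9E77", "#7570B3", "#999999"
)

new_color_scheme <- function(colors, source) {
  colors <- toupper(colors)
  ok <- grepl("^#[0-9A-F]{6}$", colors)
  if (!all(ok)) {
    stop("invalid hex color(s): ", paste(colors[!ok], collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colors)) {
    stop("color scheme contains duplicate colors", call. = FALSE)
  }
  structure(list(colors = colors, source = source), class = "color_scheme")
}

#' @export
print.color_scheme <- function(x, ...) {
  cat(sprintf("color scheme (%s): %s\n", x$source,
              paste(x$colors, collapse = " ")))
  invisible(x)
}

#' Default categorical palette for K ancestries
#'
#' Deterministic in `k`: the first `min(k, 12)` colors come from a fixed
#' curated categorical palette; any further colors are generated by an
#' evenly spaced hue rotation. No two colors are identical.
#'
#' @param k Number of ancestries, at least 2.
#' @return A `"color_scheme"` with `k` hex colors.
#' @export
default_palette <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 2) {
    stop("'k' must be a single integer >= 2", call. = FALSE)
  }
  k <- as.integer(k)
  cols <- .base_palette[seq_len(min(k, length(.base_palette)))]
  if (k > length(.base_palette)) {
    extra <- k - length(.base_palette)
    hues <- ((seq_len(extra) - 1) / extra + 0.04) %% 1
    more <- grDevices::hsv(h = hues, s = 0.62, v = 0.82)
    # nudge value on the (unlikely) collision with a curated color
    for (i in seq_along(more)) {
      while (more[i] %in% c(cols, more[seq_len(i - 1L)])) {
        more[i] <- grDevices::hsv(h = hues[i], s = 0.62,
                                  v = 0.82 - 0.02 * i)
      }
    }
    cols <- c(cols, more)
  }
  new_color_scheme(cols, source = "default")
}

#' Read a color scheme file
#'
#' Parses the format written by [write_color_scheme()]: one line per
#' ancestry with the 1-based ancestry index and a `#RRGGBB` hex color,
#' whitespace-separated. The entry count must equal `k`.
#'
#' @param path Path to the color scheme file.
#' @param k Expected number of ancestries.
#' @return A `"color_scheme"` with `source = "user_file"`.
#' @export
read_color_scheme <- function(path, k) {
  if (!file.exists(path)) {
    stop("color scheme file not found: ", path, call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  lines <- trimws(raw[nzchar(trimws(raw))])
  if (length(lines) != k) {
    stop(sprintf(
      "color scheme file '%s' has %d entries but the data has K = %d ancestries",
      path, length(lines), k
    ), call. = FALSE)
  }
  tok <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(tok) < 2L
  if (any(bad)) {
    stop("malformed color scheme line: '", lines[which(bad)[1L]], "'",
         call. = FALSE)
  }
  idx <- suppressWarnings(as.integer(vapply(tok, `[[`, character(1), 1L)))
  cols <- vapply(tok, `[[`, character(1), 2L)
  if (anyNA(idx) || !identical(sort(idx), seq_len(k))) {
    stop("color scheme indices must be 1..K, each exactly once",
         call. = FALSE)
  }
  new_color_scheme(cols[order(idx)], source = "user_file")
}

#' Write a color scheme file
#'
#' One line per ancestry: the 1-based ancestry index (matching Q-file column
#' order) and the hex color, tab-separated. The file is accepted by
#' [read_color_scheme()] in a later run.
#'
#' @param scheme A `"color_scheme"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_color_scheme <- function(scheme, path) {
  writeLines(sprintf("%d\t%s", seq_along(scheme$colors), scheme$colors),
             path)
  invisible(path)
}

# Primitive table shared by the plot spec and the renderer. One row per
# drawn primitive; screen angles in degrees (unwrapped), radii in figure
# units. Zero-extent segments and pie slices are skipped.
build_primitives <- function(layout, scheme, separators = TRUE) {
  geom <- layout$geometry
  if (length(scheme$colors) != layout$n_ancestries) {
    stop(sprintf("color scheme has %d colors but the data has K = %d",
                 length(scheme$colors), layout$n_ancestries), call. = FALSE)
  }
  prim <- function(type, ref, a0, a1, r0, r1, color, text = "",
                   rotation = NA_real_, flip = NA) {
    data.frame(type = type, ref = ref, a0 = a0, a1 = a1, r0 = r0, r1 = r1,
               color = color, text = text, rotation = rotation, flip = flip,
               stringsAsFactors = FALSE)
  }
  out <- list()

  w <- layout$wedges
  seg <- layout$segments
  # join wedge angles onto segments (segments are in wedge order, K per wedge)
  k <- layout$n_ancestries
  a0 <- rep(offset_to_screen(w$start_deg, geom), each = k)
  a1 <- rep(offset_to_screen(w$end_deg, geom), each = k)
  keep <- (seg$f1 - seg$f0) > 0
  if (any(keep)) {
    r0 <- geom$inner_radius +
      seg$f0 * (geom$outer_radius - geom$inner_radius)
    r1 <- geom$inner_radius +
      seg$f1 * (geom$outer_radius - geom$inner_radius)
    out$segments <- prim("sector",
                         sprintf("%d:%d", seg$row_index, seg$ancestry)[keep],
                         a0[keep], a1[keep], r0[keep], r1[keep],
                         scheme$colors[seg$ancestry[keep]])
  }

  if (isTRUE(separators) && nrow(layout$populations) > 1L) {
    sa <- offset_to_screen(layout$separators, geom)
    out$separators <- prim("line", sprintf("sep%d", seq_along(sa)),
                           sa, sa, geom$inner_radius, geom$outer_radius,
                           "#000000")
  }

  lab <- layout$labels
  out$labels <- prim("text", lab$label,
                     lab$screen_deg, lab$screen_deg,
                     geom$label_radius, geom$label_radius,
                     "#000000", text = lab$label,
                     rotation = lab$rotation, flip = lab$flip)

  if (!is.null(layout$center_pie)) {
    cp <- layout$center_pie
    keep <- (cp$end_deg - cp$start_deg) > 0
    if (any(keep)) {
      out$pie <- prim("pie", sprintf("pie%d", cp$ancestry[keep]),
                      offset_to_screen(cp$start_deg[keep], geom),
                      offset_to_screen(cp$end_deg[keep], geom),
                      0, geom$pie_radius,
                      scheme$colors[cp$ancestry[keep]])
    }
  }
  do.call(rbind, out)
}

fmt6 <- function(x) {
  x <- round(x, 6)
  x[x == 0] <- 0  # avoid "-0.000000"
  sprintf("%.6f", x)
}

#' Canonical plot specification
#'
#' Produces an ordered, canonical textual description of every primitive the
#' figure draws (annular sectors, separator lines, labels, pie slices) with
#' coordinates rounded to 6 decimals. The serialization is byte-identical
#' across runs for identical inputs, which makes it the package's golden
#' surface for reproducibility testing: the spec fully determines the
#' drawing.
#'
#' @param layout A `"circular_layout"`.
#' @param scheme A `"color_scheme"` with K colors.
#' @param separators Draw black radial lines at population boundaries.
#' @return Character vector of tab-separated lines, one per primitive, with
#'   a single header line.
#' @export
plot_spec <- function(layout, scheme, separators = TRUE) {
  prims <- build_primitives(layout, scheme, separators)
  header <- sprintf("plotspec\tv1\tP=%d\tN=%d\tK=%d",
                    nrow(layout$populations), layout$n_individuals,
                    layout$n_ancestries)
  body <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                  prims$type, prims$ref,
                  fmt6(prims$a0), fmt6(prims$a1),
                  fmt6(prims$r0), fmt6(prims$r1),
                  prims$color, prims$text,
                  ifelse(is.na(prims$rotation), "", fmt6(prims$rotation)),
                  ifelse(is.na(prims$flip), "", ifelse(prims$flip, "1", "0")))
  c(header, body)
}

#' Write a plot specification to a file
#' @param spec Character vector from [plot_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plot_spec <- function(spec, path) {
  writeLines(spec, path)
  invisible(path)
}

draw_sector <- function(a0, a1, r0, r1, col) {
  n <- max(2L, ceiling(abs(a1 - a0) / 2) + 1L)
  th <- seq(a0, a1, length.out = n) * pi / 180
  if (r0 <= 0) {
    x <- c(0, r1 * cos(th))
    y <- c(0, r1 * sin(th))
  } else {
    x <- c(r1 * cos(th), r0 * cos(rev(th)))
    y <- c(r1 * sin(th), r0 * sin(rev(th)))
  }
  graphics::polygon(x, y, col = col, border = NA)
}

#' Render the circular ancestry figure
#'
#' Draws the layout to a PDF, PNG or SVG file. Every individual is a stack
#' of K annular segments colored by ancestry; population boundaries are
#' optionally marked with black radial lines; the central pie is drawn when
#' the layout carries one. The drawing consists of exactly the primitives
#' listed by [plot_spec()], which is also returned.
#'
#' @param layout A `"circular_layout"`.
#' @param scheme A `"color_scheme"` with K colors.
#' @param file Output figure path.
#' @param format `"pdf"`, `"png"` or `"svg"`; defaults to the extension of
#'   `file`.
#' @param separators Draw black radial lines at population boundaries.
#' @param dpi Raster resolution for PNG output.
#' @param label_cex Label character expansion; by default shrinks with the
#'   number of populations.
#' @return The plot spec lines, invisibly.
#' @export
render_figure <- function(layout, scheme, file,
                          format = c("auto", "pdf", "png", "svg"),
                          separators = TRUE, dpi = 300, label_cex = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(file))
    if (!format %in% c("pdf", "png", "svg")) {
      stop("cannot infer figure format from '", file,
           "'; use format = \"pdf\", \"png\" or \"svg\"", call. = FALSE)
    }
  }
  prims <- build_primitives(layout, scheme, separators)
  p_count <- nrow(layout$populations)
  if (is.null(label_cex)) {
    label_cex <- max(0.25, min(0.9, 60 / p_count))
  }

  switch(format,
    pdf = grDevices::pdf(file, width = 10, height = 10),
    png = grDevices::png(file, width = 10 * dpi, height = 10 * dpi,
                         res = dpi, type = "cairo"),
    svg = grDevices::svg(file, width = 10, height = 10)
  )
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  lim <- layout$geometry$label_radius * 1.22
  graphics::plot.window(xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1)

  for (type in c("sector", "pie")) {
    sub <- prims[prims$type == type, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      draw_sector(sub$a0[i], sub$a1[i], sub$r0[i], sub$r1[i], sub$color[i])
    }
  }
  sub <- prims[prims$type == "line", , drop = FALSE]
  if (nrow(sub) > 0L) {
    th <- sub$a0 * pi / 180
    graphics::segments(sub$r0 * cos(th), sub$r0 * sin(th),
                       sub$r1 * cos(th), sub$r1 * sin(th),
                       col = "black", lwd = 0.4)
  }
  sub <- prims[prims$type == "text", , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    th <- sub$a0[i] * pi / 180
    graphics::text(sub$r0[i] * cos(th), sub$r0[i] * sin(th),
                   labels = sub$text[i], srt = sub$rotation[i],
                   adj = if (isTRUE(sub$flip[i])) c(1, 0.5) else c(0, 0.5),
                   cex = label_cex, xpd = NA)
  }
  invisible(plot_spec(layout, scheme, separators))
}
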