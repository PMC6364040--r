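# Resolved polar geometry for the circular stacked-bar plot. Angular
# positions are tracked in two frames: "offset" degrees t in [0, 360),
# measured along the winding direction from the starting angle, and "screen"
# degrees in the usual mathematical convention (0 = east, counterclockwise
# positive) used for drawing. The circle has fixed perimeter: every
# population receives 360/P degrees regardless of how many individuals it
# holds, and each individual's bar is length-fixed with radial segments
# proportional to its ancestry fractions.

#' Geometry configuration for the circular plot
#'
#' @param start_angle Screen angle (degrees) where the first population
#'   begins; 90 is the top of the circle.
#' @param direction `"clockwise"` or `"counterclockwise"` winding.
#' @param inner_radius,outer_radius Radial extent of the bars (relative
#'   units); a bar of an individual always spans this full range.
#' @param label_radius Radius at which population labels are anchored.
#' @param pie_radius Radius of the central highlight pie.
#' @return A list of class `"circle_geometry"`.
#' @export
circle_geometry <- function(start_angle = 90,
                            direction = c("clockwise", "counterclockwise"),
                            inner_radius = 0.45, outer_radius = 1.0,
                            label_radius = 1.04, pie_radius = 0.40) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(start_angle), length(start_angle) == 1L,
            inner_radius > 0, outer_radius > inner_radius,
            label_radius > 0, pie_radius > 0)
  structure(list(start_angle = start_angle, direction = direction,
                 inner_radius = inner_radius, outer_radius = outer_radius,
                 label_radius = label_radius, pie_radius = pie_radius),
            class = "circle_geometry")
}

# offset degrees along the winding direction -> screen degrees (unwrapped)
offset_to_screen <- function(t, geometry) {
  if (geometry$direction == "clockwise") geometry$start_angle - t
  else geometry$start_angle + t
}

#' Compute the resolved circular layout
#'
#' Allocates equal angular spans of 360/P degrees to the P populations of a
#' plotting order, splits each span into equal-width wedges for the
#' population's individuals, partitions each wedge radially in proportion to
#' the individual's ancestry fractions, and places separators and labels.
#' When a target population is named, its mean composition becomes the
#' central pie.
#'
#' @param order A `"plot_order"` from [resolve_order()].
#' @param matrix The ancestry matrix the order indexes into.
#' @param target Optional label of a population in `order` to highlight as
#'   the central pie.
#' @param geometry A [circle_geometry()].
#' @param center_pie Optional precomputed pie slice data frame from
#'   [compute_center_pie()]; used when the highlighted population is not
#'   part of the ring. Ignored if `target` is given.
#' @return An object of class `"circular_layout"`: a list with data frames
#'   `populations` (label, start/end offset degrees), `wedges` (row index,
#'   population, start/end offset degrees), `segments` (row index, ancestry,
#'   radial fractions f0/f1 of the bar), `separators` (offset degrees of the
#'   population boundaries), `labels` (see [place_labels()]), the optional
#'   `center_pie`, and the `geometry`.
#' @export
compute_layout <- function(order, matrix, target = NULL,
                           geometry = circle_geometry(),
                           center_pie = NULL) {
  if (!inherits(order, "plot_order") || length(order$populations) == 0L) {
    stop("'order' must be a non-empty plot_order", call. = FALSE)
  }
  pops <- order$populations
  p_count <- length(pops)
  span <- 360 / p_count
  labels <- vapply(pops, `[[`, character(1), "label")

  populations <- data.frame(
    label = labels,
    start_deg = (seq_len(p_count) - 1) * span,
    end_deg = seq_len(p_count) * span,
    stringsAsFactors = FALSE
  )

  wedge_list <- vector("list", p_count)
  for (i in seq_len(p_count)) {
    members <- pops[[i]]$member_rows
    n <- length(members)
    w <- span / n
    wedge_list[[i]] <- data.frame(
      row_index = members,
      population = labels[i],
      start_deg = populations$start_deg[i] + (seq_len(n) - 1) * w,
      end_deg = populations$start_deg[i] + seq_len(n) * w,
      stringsAsFactors = FALSE
    )
  }
  wedges <- do.call(rbind, wedge_list)

  vals <- unclass(matrix)
  k <- ncol(vals)
  seg_rows <- rep(wedges$row_index, each = k)
  f1 <- unlist(lapply(wedges$row_index, function(r) {
    cs <- cumsum(vals[r, ])
    cs / cs[k]  # length-fixed bar: fractions always fill [0, 1]
  }), use.names = FALSE)
  f0 <- f1 - unlist(lapply(wedges$row_index, function(r) {
    vals[r, ] / sum(vals[r, ])
  }), use.names = FALSE)
  segments <- data.frame(
    row_index = seg_rows,
    ancestry = rep(seq_len(k), times = nrow(wedges)),
    f0 = f0, f1 = f1
  )

  separators <- populations$start_deg

  pie <- NULL
  if (!is.null(target)) {
    hit <- which(labels == target)
    if (length(hit) == 0L) {
      stop("target population '", target, "' is not in the plotting order",
           call. = FALSE)
    }
    pie <- pie_slices(pops[[hit]]$mean_proportions)
  } else if (!is.null(center_pie)) {
    pie <- center_pie
  }

  layout <- structure(
    list(populations = populations, wedges = wedges, segments = segments,
         separators = separators, labels = NULL, center_pie = pie,
         geometry = geometry, n_ancestries = k,
         n_individuals = nrow(wedges)),
    class = "circular_layout"
  )
  layout$labels <- place_labels(layout)
  layout
}

#' @export
print.circular_layout <- function(x, ...) {
  cat(sprintf(
    "circular layout: %d populations (%.4f degrees each), %d individuals, K = %d%s\n",
    nrow(x$populations), 360 / nrow(x$populations), x$n_individuals,
    x$n_ancestries,
    if (is.null(x$center_pie)) "" else ", center pie"
  ))
  invisible(x)
}

pie_slices <- function(mean_proportions) {
  k <- length(mean_proportions)
  ang <- 360 * mean_proportions / sum(mean_proportions)
  cs <- cumsum(ang)
  data.frame(ancestry = seq_len(k),
             start_deg = c(0, cs[-k]),
             end_deg = cs)
}

#' Pie slices for a highlighted population
#'
#' The central pie shows the mean ancestry composition of the target
#' population: the slice for ancestry a spans 360 times its mean proportion,
#' slices emitted in ancestry-index order from the starting angle. For a
#' single-individual target this is the individual's own composition.
#'
#' @param dataset An `"ancestry_dataset"`.
#' @param target A group label present in the dataset.
#' @return Data frame with columns `ancestry`, `start_deg`, `end_deg`
#'   (offset degrees; zero-width slices are kept for zero proportions).
#' @export
compute_center_pie <- function(dataset, target) {
  rows <- which(dataset$individuals$group_label == target)
  if (length(rows) == 0L) {
    stop("unknown target population: ", target, call. = FALSE)
  }
  pie_slices(colMeans(unclass(dataset$Q)[rows, , drop = FALSE]))
}

#' Place population labels
#'
#' Each population gets one label anchored at the angular midpoint of its
#' span at the label radius, rotated to read radially outward. Labels that
#' land on the left half of the circle (screen angles between 90 and 270
#' degrees) are flipped 180 degrees with the anchor swapped so the text
#' still reads outward legibly.
#'
#' @param layout A `"circular_layout"`.
#' @param geometry Geometry to use; defaults to the layout's own.
#' @return Data frame with columns `label`, `mid_deg` (offset degrees),
#'   `screen_deg` (wrapped to \[0, 360)), `rotation` (text rotation in
#'   degrees) and `flip` (logical).
#' @export
place_labels <- function(layout, geometry = layout$geometry) {
  mid <- (layout$populations$start_deg + layout$populations$end_deg) / 2
  screen <- offset_to_screen(mid, geometry) %% 360
  flip <- screen > 90 & screen < 270
  rotation <- ifelse(flip, screen - 180, screen)
  data.frame(label = layout$populations$label,
             mid_deg = mid, screen_deg = screen,
             rotation = rotation, flip = flip,
             stringsAsFactors = FALSE)
}
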