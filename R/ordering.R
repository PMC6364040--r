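# Representative-ancestry sorting: each population's representative ancestry
# is the component with the largest mean proportion; populations are bucketed
# into K groups by that index, groups are laid out in ascending ancestry
# index, populations within a group in descending representative proportion,
# and individuals within a population in descending order of the
# population's representative component.

#' Summarize one population
#'
#' Computes a population's mean ancestry proportion vector and its
#' representative ancestry: the component with the largest mean proportion,
#' with ties broken toward the lowest ancestry index.
#'
#' @param dataset An `"ancestry_dataset"`.
#' @param label A population (group) label present in the dataset.
#' @return An object of class `"population_summary"`: a list with `label`,
#'   `member_rows` (1-based row indices into the matrix, in file order),
#'   `mean_proportions` (length-K vector) and `representative` (1-based
#'   ancestry index).
#' @export
summarize_population <- function(dataset, label) {
  rows <- which(dataset$individuals$group_label == label)
  if (length(rows) == 0L) {
    stop("unknown population label: ", label, call. = FALSE)
  }
  mp <- colMeans(unclass(dataset$Q)[rows, , drop = FALSE])
  structure(
    list(label = label, member_rows = rows, mean_proportions = mp,
         representative = which.max(mp)),
    class = "population_summary"
  )
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("population '%s': %d individuals, representative ancestry %d (%.3f)\n",
              x$label, length(x$member_rows), x$representative,
              x$mean_proportions[x$representative]))
  invisible(x)
}

#' Bucket population summaries into K groups by representative ancestry
#'
#' @param summaries List of `"population_summary"` objects sharing one K.
#' @return A list of K lists; element g holds exactly the populations whose
#'   representative ancestry is g. Groups are in ascending ancestry index;
#'   an ancestry that is nobody's maximum yields an empty group.
#' @export
group_by_representative <- function(summaries) {
  if (length(summaries) == 0L) return(list())
  ks <- vapply(summaries, function(s) length(s$mean_proportions), integer(1))
  if (length(unique(ks)) != 1L) {
    stop("population summaries disagree on K: ",
         paste(unique(ks), collapse = ", "), call. = FALSE)
  }
  k <- ks[1L]
  groups <- vector("list", k)
  for (g in seq_len(k)) groups[[g]] <- list()
  for (s in summaries) {
    g <- s$representative
    groups[[g]] <- c(groups[[g]], list(s))
  }
  groups
}

#' Sort populations of one representative-ancestry group
#'
#' Sorts by the mean proportion of the shared representative ancestry,
#' descending; exact ties fall back to ascending lexicographic label order,
#' so the result is deterministic.
#'
#' @param group List of `"population_summary"` objects that all share the
#'   same representative ancestry.
#' @return The same summaries, sorted.
#' @export
sort_populations <- function(group) {
  if (length(group) <= 1L) return(group)
  reps <- vapply(group, function(s) s$representative, integer(1))
  if (length(unique(reps)) != 1L) {
    stop("sort_populations() requires one representative ancestry per group; got ",
         paste(sort(unique(reps)), collapse = ", "), call. = FALSE)
  }
  vals <- vapply(group, function(s) s$mean_proportions[s$representative],
                 numeric(1))
  labs <- vapply(group, function(s) s$label, character(1))
  ord <- order(-vals, labs, method = "radix")
  group[ord]
}

#' Sort a population's members for plotting
#'
#' Individuals are sorted in descending order of their own proportion of the
#' population's representative ancestry; exact ties keep the original row
#' order.
#'
#' @param population A `"population_summary"`.
#' @param matrix The ancestry matrix the summary indexes into.
#' @return `member_rows` reordered for plotting.
#' @export
sort_individuals <- function(population, matrix) {
  rows <- population$member_rows
  v <- unclass(matrix)[rows, population$representative]
  rows[order(-v, rows, method = "radix")]
}

#' Resolve the full plotting order
#'
#' Applies the automatic ordering (bucket populations by representative
#' ancestry, ascending ancestry index; descending representative proportion
#' within each bucket; individuals sorted within populations), or a custom
#' population order when one is supplied. Excluded populations are removed
#' before any ordering.
#'
#' @param dataset An `"ancestry_dataset"`.
#' @param custom_order Optional character vector of population labels. When
#'   given, the population sequence follows it exactly (populations not
#'   listed are omitted); individuals are still sorted within populations.
#' @param exclude Optional character vector of population labels to leave
#'   out of the plot.
#' @return An object of class `"plot_order"`: a list with `populations`
#'   (ordered list of `"population_summary"` objects whose `member_rows` are
#'   already in plotting order) and `individual_sequence` (the concatenated
#'   row indices).
#' @export
resolve_order <- function(dataset, custom_order = NULL, exclude = NULL) {
  labels <- population_labels(dataset)
  if (!is.null(exclude)) {
    unknown <- setdiff(exclude, labels)
    if (length(unknown) > 0L) {
      stop("cannot exclude unknown population label(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    labels <- setdiff(labels, exclude)
  }
  if (length(labels) == 0L) {
    stop("no populations left to plot after exclusions", call. = FALSE)
  }
  if (!is.null(custom_order)) {
    unknown <- setdiff(custom_order, population_labels(dataset))
    if (length(unknown) > 0L) {
      stop("unknown population label(s) in custom order: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(custom_order)) {
      stop("custom order lists label(s) more than once: ",
           paste(unique(custom_order[duplicated(custom_order)]),
                 collapse = ", "), call. = FALSE)
    }
    seq_labels <- custom_order[custom_order %in% labels]
    if (length(seq_labels) == 0L) {
      stop("custom order and exclusions leave no populations to plot",
           call. = FALSE)
    }
    pops <- lapply(seq_labels, summarize_population, dataset = dataset)
  } else {
    summaries <- lapply(labels, summarize_population, dataset = dataset)
    groups <- group_by_representative(summaries)
    pops <- do.call(c, lapply(groups, sort_populations))
  }
  pops <- lapply(pops, function(p) {
    p$member_rows <- sort_individuals(p, dataset$Q)
    p
  })
  structure(
    list(populations = pops,
         individual_sequence = unlist(lapply(pops, `[[`, "member_rows"),
                                      use.names = FALSE)),
    class = "plot_order"
  )
}

#' @export
print.plot_order <- function(x, ...) {
  cat(sprintf("plot order: %d populations, %d individuals\n",
              length(x$populations), length(x$individual_sequence)))
  invisible(x)
}
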