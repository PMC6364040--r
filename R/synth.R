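# Synthetic admixture datasets: population centers on the K-simplex drawn
# from a flat Dirichlet, individuals drawn from a Dirichlet concentrated
# around their population's center. This emulates the statistical structure
# of a Q matrix from a clustering run, so every stage of the pipeline can be
# exercised without external data.

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate an admixture dataset
#'
#' Draws a random ancestry-proportion center for each population from a flat
#' Dirichlet over the K-simplex, then draws each individual's proportion
#' vector from `Dirichlet(concentration * center)`. Larger `concentration`
#' means individuals cluster more tightly around their population's center.
#' Rows are renormalized so they sum to one exactly. The defaults mirror the
#' scale of a large published global survey: 203 populations with about a
#' dozen sampled individuals each and K = 8 assumed ancestral sources.
#'
#' @param n_populations Number of populations.
#' @param k Number of ancestral source populations (K), at least 2.
#' @param sizes Optional integer vector of per-population sample sizes
#'   (length `n_populations`). When `NULL`, sizes are drawn uniformly from
#'   `size_range`.
#' @param size_range Inclusive range to draw sizes from when `sizes` is
#'   `NULL`.
#' @param concentration Positive Dirichlet concentration about each
#'   population center; 50 gives the moderate within-population spread
#'   typical of real clustering output.
#' @param seed Integer seed; identical seed and configuration reproduce the
#'   dataset exactly. `NULL` uses the current RNG state.
#' @return An `"ancestry_dataset"` with populations labelled
#'   `Pop001, Pop002, ...` and individuals `Ind00001, ...`.
#' @export
simulate_admixture <- function(n_populations = 203, k = 8, sizes = NULL,
                               size_range = c(5, 18), concentration = 50,
                               seed = NULL) {
  stopifnot(n_populations >= 1, k >= 2, concentration > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(sizes)) {
    sizes <- sample(size_range[1]:size_range[2], n_populations,
                    replace = TRUE)
  }
  stopifnot(length(sizes) == n_populations, all(sizes >= 1))
  centers <- rdirichlet(n_populations, rep(1, k))
  q <- do.call(rbind, lapply(seq_len(n_populations), function(i) {
    rdirichlet(sizes[i], concentration * centers[i, ])
  }))
  q <- q / rowSums(q)
  n <- nrow(q)
  individuals <- data.frame(
    individual_id = sprintf("Ind%05d", seq_len(n)),
    group_label = rep(sprintf("Pop%03d", seq_len(n_populations)),
                      times = sizes),
    stringsAsFactors = FALSE
  )
  ds <- bind_dataset(new_ancestry_matrix(q), individuals)
  attr(ds, "centers") <- centers  # true population centers, for testing
  ds
}

#' Per-population sizes matching the large-survey scale
#'
#' Splits `n_individuals` across `n_populations` as evenly as integer sizes
#' allow (the first populations get the remainder). The defaults give the
#' 2345-individual, 203-population composition of a typical worldwide
#' ancestry panel.
#'
#' @param n_populations Number of populations.
#' @param n_individuals Total number of individuals.
#' @return Integer vector of length `n_populations` summing to
#'   `n_individuals`.
#' @export
survey_scale_sizes <- function(n_populations = 203, n_individuals = 2345) {
  base <- n_individuals %/% n_populations
  extra <- n_individuals %% n_populations
  rep(c(base + 1L, base), c(extra, n_populations - extra))
}

#' Write a dataset as a Q file and an individual file
#'
#' Writes the two plain-text inputs in exactly the dialects the readers
#' accept: a whitespace-delimited Q matrix (full double precision, so the
#' read-back reproduces the values bit for bit) and a two-column
#' `id group` label file.
#'
#' @param dataset An `"ancestry_dataset"`.
#' @param q_path,ind_path Output paths for the matrix and the label file.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_dataset <- function(dataset, q_path, ind_path) {
  write_q_matrix(dataset$Q, q_path)
  writeLines(paste(dataset$individuals$individual_id,
                   dataset$individuals$group_label),
             ind_path)
  invisible(c(q = q_path, ind = ind_path))
}

#' Generate synthetic input files on disk
#'
#' Convenience wrapper: [simulate_admixture()] followed by
#' [write_dataset()], writing `<prefix>.Q` and `<prefix>.ind`.
#'
#' @param prefix Output path prefix.
#' @inheritParams simulate_admixture
#' @return Named character vector of the two paths, invisibly.
#' @export
generate_fixture <- function(prefix, n_populations = 203, k = 8,
                             sizes = NULL, size_range = c(5, 18),
                             concentration = 50, seed = NULL) {
  ds <- simulate_admixture(n_populations = n_populations, k = k,
                           sizes = sizes, size_range = size_range,
                           concentration = concentration, seed = seed)
  write_dataset(ds, paste0(prefix, ".Q"), paste0(prefix, ".ind"))
}
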