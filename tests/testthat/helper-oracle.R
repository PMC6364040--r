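# Independent brute-force reference for the automatic plotting order:
# bucket populations by the argmax of their mean proportion vector
# (ties -> lowest ancestry index), emit buckets in ascending ancestry
# index, populations within a bucket in descending representative
# proportion (ties -> label, C-locale ascending), individuals within a
# population in descending order of the population's representative
# column (ties -> original row). Deliberately naive and loop-based.
oracle_order <- function(Q, groups) {
  Q <- unclass(Q)
  labs <- unique(groups)
  k <- ncol(Q)
  reps <- integer(length(labs))
  repv <- numeric(length(labs))
  for (i in seq_along(labs)) {
    m <- colMeans(Q[groups == labs[i], , drop = FALSE])
    reps[i] <- which.max(m)
    repv[i] <- m[reps[i]]
  }
  ordered_labels <- character(0)
  for (g in seq_len(k)) {
    members <- which(reps == g)
    if (length(members) == 0L) next
    members <- members[order(-repv[members], labs[members], method = "radix")]
    ordered_labels <- c(ordered_labels, labs[members])
  }
  rows <- integer(0)
  for (l in ordered_labels) {
    mem <- which(groups == l)
    v <- Q[mem, reps[match(l, labs)]]
    rows <- c(rows, mem[order(-v, mem, method = "radix")])
  }
  list(labels = ordered_labels, rows = rows)
}

# Random dataset for fuzzing: up to 10 populations, K in 2..6, small N.
random_dataset <- function(seed, max_pop_size = 5) {
  set.seed(seed)
  p <- sample(1:10, 1)
  k <- sample(2:6, 1)
  sizes <- sample(seq_len(max_pop_size), p, replace = TRUE)
  simulate_admixture(n_populations = p, k = k, sizes = sizes,
                     concentration = stats::runif(1, 2, 80))
}

# Tiny hand-built dataset from an explicit matrix and label vector.
make_dataset <- function(values, groups, ids = NULL) {
  m <- matrix(values, ncol = length(values) / length(groups), byrow = TRUE)
  if (is.null(ids)) ids <- sprintf("I%02d", seq_along(groups))
  bind_dataset(m, data.frame(individual_id = ids, group_label = groups,
                             stringsAsFactors = FALSE))
}

order_labels <- function(order) {
  vapply(order$populations, `[[`, character(1), "label")
}
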