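test_that("population summaries take the mean and its argmax", {
  ds <- make_dataset(c(0.2, 0.8,
                       0.4, 0.6), c("P", "P"))
  s <- summarize_population(ds, "P")
  expect_equal(s$mean_proportions, c(0.3, 0.7), ignore_attr = TRUE)
  expect_equal(s$representative, 2L)
  expect_equal(s$member_rows, c(1L, 2L))

  ds1 <- make_dataset(c(1, 0, 0), "Solo")
  s1 <- summarize_population(ds1, "Solo")
  expect_equal(s1$mean_proportions, c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(s1$representative, 1L)

  # exact tie resolves to the lowest ancestry index
  tie <- summarize_population(make_dataset(c(0.5, 0.5), "T"), "T")
  expect_equal(tie$representative, 1L)

  expect_error(summarize_population(ds, "Nope"), "Nope")
})

test_that("populations bucket into K groups by representative ancestry", {
  ds <- make_dataset(c(0.2, 0.8,
                       0.9, 0.1,
                       0.3, 0.7), c("pop1", "pop2", "pop3"))
  sums <- lapply(c("pop1", "pop2", "pop3"), summarize_population,
                 dataset = ds)
  groups <- group_by_representative(sums)
  expect_length(groups, 2L)
  expect_equal(vapply(groups[[1]], `[[`, "", "label"), "pop2")
  expect_equal(vapply(groups[[2]], `[[`, "", "label"), c("pop1", "pop3"))

  # an ancestry that is nobody's maximum yields an empty group
  ds2 <- make_dataset(c(0.8, 0.1, 0.1,
                        0.7, 0.2, 0.1), c("A", "B"))
  g2 <- group_by_representative(lapply(c("A", "B"), summarize_population,
                                       dataset = ds2))
  expect_length(g2, 3L)
  expect_length(g2[[1]], 2L)
  expect_length(g2[[2]], 0L)
  expect_length(g2[[3]], 0L)
})

test_that("bucketing matches brute-force assignment on random data", {
  for (seed in 1:20) {
    ds <- random_dataset(seed + 500)
    labs <- population_labels(ds)
    sums <- lapply(labs, summarize_population, dataset = ds)
    groups <- group_by_representative(sums)
    for (g in seq_along(groups)) {
      got <- vapply(groups[[g]], `[[`, character(1), "label")
      want <- labs[vapply(sums, `[[`, integer(1), "representative") == g]
      expect_setequal(got, want)
    }
  }
})

test_that("populations sort by descending representative proportion", {
  mk <- function(label, p) {
    structure(list(label = label, member_rows = 1L,
                   mean_proportions = c(p, 1 - p), representative = 1L),
              class = "population_summary")
  }
  got <- sort_populations(list(mk("x", 0.6), mk("y", 0.9), mk("z", 0.7)))
  expect_equal(vapply(got, `[[`, "", "label"), c("y", "z", "x"))

  # exact ties break by ascending label
  tied <- sort_populations(list(mk("B", 0.8), mk("A", 0.8)))
  expect_equal(vapply(tied, `[[`, "", "label"), c("A", "B"))

  mixed <- list(mk("x", 0.6),
                structure(list(label = "w", member_rows = 2L,
                               mean_proportions = c(0.3, 0.7),
                               representative = 2L),
                          class = "population_summary"))
  expect_error(sort_populations(mixed), "one representative ancestry")

  # random groups agree with a naive comparison sort
  set.seed(42)
  for (i in 1:20) {
    group <- lapply(seq_len(8), function(j) mk(sprintf("p%02d", j),
                                               stats::runif(1)))
    got <- vapply(sort_populations(group), `[[`, "", "label")
    vals <- vapply(group, function(s) s$mean_proportions[1], numeric(1))
    labs <- vapply(group, `[[`, "", "label")
    want <- labs[order(-vals, labs, method = "radix")]
    expect_equal(got, want)
  }
})

test_that("individuals sort on the population's representative column", {
  ds <- make_dataset(c(0.5, 0.5,
                       0.1, 0.9,
                       0.3, 0.7), c("P", "P", "P"))
  s <- summarize_population(ds, "P")
  expect_equal(s$representative, 2L)
  expect_equal(sort_individuals(s, ds$Q), c(2L, 3L, 1L))

  # identical members keep original file order
  ds_eq <- make_dataset(rep(c(0.4, 0.6), 4), rep("P", 4))
  s_eq <- summarize_population(ds_eq, "P")
  expect_equal(sort_individuals(s_eq, ds_eq$Q), 1:4)

  # random members agree with a brute-force sort
  set.seed(7)
  for (i in 1:10) {
    n <- 20
    q <- matrix(stats::runif(n * 3), n)
    q <- q / rowSums(q)
    dsr <- bind_dataset(q, data.frame(individual_id = sprintf("i%d", 1:n),
                                      group_label = "P"))
    sr <- summarize_population(dsr, "P")
    want <- order(-q[, sr$representative], seq_len(n))
    expect_equal(sort_individuals(sr, dsr$Q), want)
  }
})

test_that("resolve_order honors custom orders and exclusions", {
  ds <- make_dataset(c(0.9, 0.1,
                       0.2, 0.8,
                       0.6, 0.4), c("A", "B", "C"))
  custom <- resolve_order(ds, custom_order = c("C", "A", "B"))
  expect_equal(order_labels(custom), c("C", "A", "B"))

  excl <- resolve_order(ds, exclude = "B")
  expect_equal(sort(order_labels(excl)), c("A", "C"))
  expect_false(2L %in% excl$individual_sequence)

  expect_error(resolve_order(ds, custom_order = c("A", "Zed")), "Zed")
  expect_error(resolve_order(ds, exclude = "Zed"), "Zed")
  expect_error(resolve_order(ds, custom_order = c("A", "A")), "more than once")
})

test_that("automatic ordering equals the brute-force oracle on random data", {
  for (seed in 1:100) {
    ds <- random_dataset(seed)
    want <- oracle_order(ds$Q, ds$individuals$group_label)
    got <- resolve_order(ds)
    expect_equal(order_labels(got), want$labels)
    expect_equal(got$individual_sequence, want$rows)
  }
})

test_that("the individual sequence is always a permutation of the kept rows", {
  for (seed in 1:25) {
    ds <- random_dataset(seed + 200)
    ord <- resolve_order(ds)
    expect_equal(sort(ord$individual_sequence), seq_len(nrow(ds$Q)))
    labs <- population_labels(ds)
    if (length(labs) > 1) {
      drop <- labs[1]
      kept_rows <- which(ds$individuals$group_label != drop)
      ord2 <- resolve_order(ds, exclude = drop)
      expect_equal(sort(ord2$individual_sequence), kept_rows)
    }
  }
})

test_that("ordering is invariant to shuffling the input rows", {
  for (seed in 1:10) {
    ds <- random_dataset(seed + 900)
    n <- nrow(ds$Q)
    set.seed(seed)
    perm <- sample(n)
    ds_shuf <- bind_dataset(unclass(ds$Q)[perm, , drop = FALSE],
                            ds$individuals[perm, ])
    a <- resolve_order(ds)
    b <- resolve_order(ds_shuf)
    expect_equal(order_labels(a), order_labels(b))
    # same individuals in the same plotted order (continuous values:
    # exact ties that would engage the row-index tie-break are absent)
    expect_equal(ds$individuals$individual_id[a$individual_sequence],
                 ds_shuf$individuals$individual_id[b$individual_sequence])
  }
})
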