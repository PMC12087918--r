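test_that("window statistics match naive per-statistic formulas", {
  set.seed(12)
  x <- rnorm(20)
  m <- cbind(a = x, b = seq(1, 5.75, by = 0.25))
  v <- stat_features(m)
  mu <- sum(x) / 20
  expect_equal(v[["a.mean"]], mu)
  expect_equal(v[["a.variance"]], sum((x - mu)^2) / 20)
  expect_equal(v[["a.skewness"]],
               (sum((x - mu)^3) / 20) / (sum((x - mu)^2) / 20)^1.5)
  expect_equal(v[["a.kurtosis"]],
               (sum((x - mu)^4) / 20) / (sum((x - mu)^2) / 20)^2)
  expect_equal(v[["a.abs_energy"]], sum(x^2))
  expect_equal(v[["a.mean_abs_change"]], sum(abs(diff(x))) / 19)
  expect_equal(v[["a.acf2"]],
               sum((x[1:18] - mu) * (x[3:20] - mu)) / sum((x - mu)^2))
  expect_equal(v[["a.count_above_mean"]], sum(x > mu))
  # linear ramp: mean absolute change equals the constant step
  expect_equal(v[["b.mean_abs_change"]], 0.25)
  # constant column: variance 0, autocorrelations undefined
  vc <- stat_features(cbind(const = rep(2, 10)))
  expect_equal(vc[["const.variance"]], 0)
  expect_true(is.nan(vc[["const.acf1"]]))
})

test_that("dirty statistics are dropped consistently across samples", {
  fm <- structure(list(values = cbind(rnorm(30), rep(1, 30)),
                       labels = rep(1:2, 15),
                       layout = NULL, subseries_duration = 1),
                  class = "pg_features")
  wins <- slide_windows(fm, 5)
  st <- stat_feature_table(fm, wins, 5)
  expect_gt(st$dropped, 0)               # constant column loses acf etc.
  expect_true(all(is.finite(st$table)))
  expect_identical(nrow(st$table), nrow(wins))
})

test_that("relevance filter keeps label-linked features, drops constants", {
  set.seed(113)
  n <- 200
  labels <- rep(1:2, each = n / 2)
  tab <- cbind(informative = labels + rnorm(n, sd = 0.2),
               constant = rep(3, n),
               noise = rnorm(n))
  st <- structure(list(table = tab, labels = labels, index = 1:n),
                  class = "pg_stat_table")
  out <- select_relevant(st)
  expect_true("informative" %in% colnames(out$table))
  expect_false("constant" %in% colnames(out$table))
  expect_false("noise" %in% colnames(out$table))
  # order invariance
  perm <- sample(n)
  st2 <- structure(list(table = tab[perm, ], labels = labels[perm],
                        index = (1:n)[perm]),
                   class = "pg_stat_table")
  expect_setequal(colnames(select_relevant(st2)$table),
                  colnames(out$table))
  # all-noise table falls back with a warning
  st3 <- st
  st3$table <- matrix(rnorm(n * 3), n,
                      dimnames = list(NULL, paste0("n", 1:3)))
  expect_warning(out3 <- select_relevant(st3, fallback_k = 2), "no feature")
  expect_identical(ncol(out3$table), 2L)
})

test_that("mmd satisfies its axioms and closed forms", {
  set.seed(14)
  u <- matrix(rnorm(20), 10, 2)
  v <- matrix(rnorm(20, mean = 1), 10, 2)
  expect_equal(mmd(u, u, 1), 0, tolerance = 1e-12)
  expect_equal(mmd(u, v, 1.3), mmd(v, u, 1.3), tolerance = 1e-12)
  expect_gte(mmd(u, v, 1), 0)
  # singletons at squared distance 2 sigma^2: 2 (1 - e^-1)
  sigma <- 0.7
  expect_equal(mmd(matrix(0, 1, 1), matrix(sqrt(2) * sigma, 1, 1), sigma),
               2 * (1 - exp(-1)), tolerance = 1e-12)
  # agrees with the explicit three-term loop
  expect_equal(mmd(u, v, 0.9), naive_mmd(u, v, 0.9), tolerance = 1e-12)
  # monotone in Gaussian mean separation
  seps <- c(0, 0.5, 1, 2, 4)
  vals <- vapply(seps, function(s) {
    set.seed(15)
    mmd(matrix(rnorm(200), 100, 2), matrix(rnorm(200, mean = s), 100, 2), 1)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(mmd(u, v, 0), "sigma")
})

test_that("merge rule: a small remnant cluster joins its neighbour", {
  # one class with planted sizes ~[10, 400]: single merged domain of 410
  set.seed(16)
  tab <- rbind(matrix(rnorm(10 * 2, mean = 5), 10, 2),
               matrix(rnorm(400 * 2), 400, 2))
  st <- structure(list(table = cbind(tab, tab[, 1] + tab[, 2]),
                       labels = rep(1L, 410), index = 1:410),
                  class = "pg_stat_table")
  part <- segment_domains(st, k_init = 2, delta1 = 50, delta2 = 300,
                          seed = 1)
  expect_identical(unname(attr(part, "k_per_class")), 1L)
  expect_identical(nrow(part), 410L)
})

test_that("segmentation recovers well-separated regimes and is order-invariant", {
  set.seed(17)
  n_per <- 120
  mk_class <- function(centre_shift) {
    rbind(matrix(rnorm(n_per * 3, mean = 0 + centre_shift), n_per, 3),
          matrix(rnorm(n_per * 3, mean = 8 + centre_shift), n_per, 3))
  }
  tab <- rbind(mk_class(0), mk_class(1))
  labels <- rep(1:2, each = 2 * n_per)
  truth <- rep(rep(1:2, each = n_per), 2)
  st <- structure(list(table = tab, labels = labels,
                       index = seq_len(nrow(tab))),
                  class = "pg_stat_table")
  part <- segment_domains(st, k_init = 4, delta1 = 30, delta2 = 100,
                          seed = 2)
  expect_identical(unname(attr(part, "k_per_class")), c(2L, 2L))
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(
    paste(part$class, part$domain),
    paste(labels[part$index], truth[part$index]))
  expect_gte(ari, 0.9)
  # every sample assigned exactly once
  expect_setequal(part$index, st$index)
  # invariant to sample order under the same seed
  perm <- sample(nrow(tab))
  st2 <- structure(list(table = tab[perm, ], labels = labels[perm],
                        index = st$index[perm]),
                   class = "pg_stat_table")
  part2 <- segment_domains(st2, k_init = 4, delta1 = 30, delta2 = 100,
                           seed = 2)
  m <- match(part$index, part2$index)
  expect_identical(part$domain, part2$domain[m])
})

test_that("degenerate classes collapse to a single domain", {
  st <- structure(list(table = matrix(1, 80, 3), labels = rep(1L, 80),
                       index = 1:80),
                  class = "pg_stat_table")
  part <- segment_domains(st, k_init = 4, delta1 = 10, delta2 = 40, seed = 1)
  expect_identical(unname(attr(part, "k_per_class")), 1L)
})
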