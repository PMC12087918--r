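#' Statistical window features for domain segmentation
#'
#' For each feature column of a `W x F` window computes a fixed catalog of 13
#' summary statistics: mean, variance, skewness, kurtosis, min, max, median,
#' absolute energy, mean absolute change, lag-1..3 autocorrelation, and count
#' above mean. Statistics that are undefined on a column (e.g.
#' autocorrelation of a constant) come out non-finite and are dropped
#' consistently across samples by [stat_feature_table()].
#'
#' @param m numeric matrix (`W x F` window slice).
#' @return named numeric vector of `13 * F` statistics.
#' @export
stat_features <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 1L)
  out <- apply(m, 2L, function(x) {
    n <- length(x)
    mu <- mean(x)
    dev <- x - mu
    s2 <- mean(dev^2)              # population variance
    s <- sqrt(s2)
    acf_k <- function(k) {
      if (n <= k || s2 == 0) return(NaN)
      sum(dev[1:(n - k)] * dev[(1 + k):n]) / (n * s2)
    }
    c(mean = mu,
      variance = s2,
      skewness = if (s > 0) mean(dev^3) / s^3 else NaN,
      kurtosis = if (s > 0) mean(dev^4) / s2^2 else NaN,
      min = min(x), max = max(x), median = median(x),
      abs_energy = sum(x^2),
      mean_abs_change = if (n > 1) mean(abs(diff(x))) else NaN,
      acf1 = acf_k(1L), acf2 = acf_k(2L), acf3 = acf_k(3L),
      count_above_mean = sum(x > mu))
  })
  stats <- rownames(out)
  cols <- colnames(m) %||% paste0("f", seq_len(ncol(m)))
  v <- as.vector(out)
  names(v) <- paste(rep(cols, each = length(stats)), stats, sep = ".")
  v
}

#' Statistical feature table of all training windows
#'
#' Applies [stat_features()] to every window and removes columns with any
#' non-finite entry, so all samples share the same clean feature set.
#'
#' @param fm a `pg_features`.
#' @param windows data frame from [slide_windows()] (or a subset of it).
#' @param window_size window size `W`.
#' @return list with `table` (n x p matrix), `labels`, `index`
#'   (class `pg_stat_table`).
#' @export
stat_feature_table <- function(fm, windows, window_size) {
  w <- as.integer(window_size)
  tab <- t(vapply(windows$index, function(i) {
    stat_features(fm$values[i:(i + w - 1L), , drop = FALSE])
  }, numeric(13L * ncol(fm$values))))
  keep <- apply(is.finite(tab), 2L, all)
  structure(list(table = tab[, keep, drop = FALSE],
                 labels = windows$label, index = windows$index,
                 dropped = sum(!keep)),
            class = "pg_stat_table")
}

# Worst-case (largest) pairwise Mann-Whitney p-value of one feature across
# classes; a relevant feature must separate every class pair.
.feature_pvalue <- function(x, labels) {
  classes <- sort(unique(labels))
  worst <- 0
  for (i in seq_along(classes)[-1L]) {
    for (j in seq_len(i - 1L)) {
      a <- x[labels == classes[i]]
      b <- x[labels == classes[j]]
      p <- if (length(unique(c(a, b))) == 1L) 1 else {
        suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
      }
      if (!is.finite(p)) p <- 1
      worst <- max(worst, p)
    }
  }
  worst
}

#' Label-relevance filter for statistical features
#'
#' Retains features whose distribution differs between classes: each feature
#' gets the worst-case p-value over pairwise rank-sum (Mann-Whitney) tests
#' across classes, the p-values are corrected with the Benjamini-Yekutieli
#' procedure, and features above the significance level are dropped. If the
#' filter would reject everything, the `fallback_k` smallest-p features are
#' kept with a warning. Selection depends only on per-feature value sets, so
#' it is invariant to sample order.
#'
#' @param st a `pg_stat_table`.
#' @param alpha significance level after BY correction.
#' @param fallback_k number of features kept if none pass.
#' @return the filtered `pg_stat_table`, with attribute `"pvalues"`.
#' @export
select_relevant <- function(st, alpha = 0.05, fallback_k = 10) {
  stopifnot(inherits(st, "pg_stat_table"))
  if (length(unique(st$labels)) < 2L) {
    stop("relevance filtering needs at least 2 classes", call. = FALSE)
  }
  p <- apply(st$table, 2L, .feature_pvalue, labels = st$labels)
  padj <- p.adjust(p, method = "BY")
  keep <- padj <= alpha
  if (!any(keep)) {
    warning("no feature passed the relevance filter; keeping the ",
            fallback_k, " strongest")
    keep <- rank(p, ties.method = "first") <= fallback_k
  }
  st$table <- st$table[, keep, drop = FALSE]
  attr(st, "pvalues") <- padj
  st
}

#' Maximum mean discrepancy between two sample sets
#'
#' The biased V-statistic with Gaussian kernel `exp(-||u - v||^2 / (2
#' sigma^2))`, diagonal terms included:
#' `MMD(U, V) = mean_k(U, U) + mean_k(V, V) - 2 mean_k(U, V)`.
#' Symmetric in its arguments, zero when `U == V`, and nonnegative.
#'
#' @param u,v numeric matrices with one sample per row (vectors are treated
#'   as single samples).
#' @param sigma kernel bandwidth (> 0).
#' @return nonnegative scalar.
#' @export
mmd <- function(u, v, sigma) {
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  if (!is.matrix(u)) u <- matrix(u, nrow = 1L)
  if (!is.matrix(v)) v <- matrix(v, nrow = 1L)
  if (nrow(u) < 1L || nrow(v) < 1L) stop("empty sample set", call. = FALSE)
  k <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    exp(-pmax(d2, 0) / (2 * sigma^2))
  }
  mean(k(u, u)) + mean(k(v, v)) - 2 * mean(k(u, v))
}

# Median pairwise-distance bandwidth heuristic.
median_bandwidth <- function(x) {
  if (nrow(x) < 2L) return(1)
  d <- as.numeric(dist(x))
  m <- median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

# KMeans++ seeding: D^2-weighted center choice (deterministic given the RNG
# state).
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  if (k > 1L) {
    for (j in 2:k) {
      if (all(d2 == 0)) {
        idx <- sample.int(n, 1L)
      } else {
        idx <- sample.int(n, 1L, prob = d2 / sum(d2))
      }
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
    }
  }
  centers
}

#' Segment same-class samples into maximally dissimilar domains
#'
#' Per class: samples are clustered in (z-scored) statistical-feature space
#' with KMeans++ into `k_init` clusters; then, while the smallest cluster is
#' below the stop threshold and more than one cluster remains, the smallest
#' cluster is merged into its nearest same-class neighbour -- by Euclidean
#' centroid distance when its size is below `delta1`, by MMD (median
#' bandwidth heuristic) when its size lies in `[delta1, delta2)` -- and the
#' centroid is recomputed. The stop threshold is `delta2` by default
#' (`stop_rule = "delta2"`), i.e. merging continues until every cluster
#' holds at least `delta2` samples or the class has collapsed to a single
#' domain; `stop_rule = "delta1"` stops at the smaller threshold. Output is
#' invariant to sample order for a fixed seed.
#'
#' @param st a `pg_stat_table` (after [select_relevant()]).
#' @param k_init initial number of clusters per class.
#' @param delta1,delta2 size thresholds (see above).
#' @param seed integer seed.
#' @param stop_rule `"delta2"` (default) or `"delta1"`.
#' @return object of class `pg_partition`: data frame with `index`
#'   (window start row), `class`, `domain`; attribute `"k_per_class"`.
#' @export
segment_domains <- function(st, k_init = 4, delta1 = 50, delta2 = 300,
                            seed = 1, stop_rule = c("delta2", "delta1")) {
  stopifnot(inherits(st, "pg_stat_table"))
  stop_rule <- match.arg(stop_rule)
  if (k_init < 1L) stop("k_init must be >= 1", call. = FALSE)
  if (delta1 >= delta2) stop("delta1 must be < delta2", call. = FALSE)
  x <- scale(st$table)
  x[, attr(x, "scaled:scale") == 0] <- 0
  x <- x[, apply(is.finite(x), 2L, all), drop = FALSE]
  classes <- sort(unique(st$labels))
  out <- vector("list", length(classes))
  k_per_class <- integer(length(classes))
  stop_at <- if (stop_rule == "delta2") delta2 else delta1
  for (ci in seq_along(classes)) {
    rows <- which(st$labels == classes[ci])
    xc <- x[rows, , drop = FALSE]
    # canonical row order (lexicographic by feature values) makes the result
    # independent of input order
    ord <- do.call(order, as.data.frame(xc))
    xc <- xc[ord, , drop = FALSE]
    rows <- rows[ord]
    n_c <- length(rows)
    if (n_c < max(2L, delta1) || n_c <= k_init) {
      assign_vec <- rep(1L, n_c)
      k_per_class[ci] <- 1L
    } else {
      set.seed(derive_seed(seed, ci))
      centers <- unique(kmeanspp_centers(xc, k_init))
      if (nrow(centers) < 2L) {
        assign_vec <- rep(1L, n_c)
        k_per_class[ci] <- 1L
        out[[ci]] <- data.frame(index = st$index[rows],
                                class = classes[ci], domain = assign_vec)
        next
      }
      km <- suppressWarnings(
        kmeans(xc, centers = centers, iter.max = 100L, algorithm = "Lloyd"))
      assign_vec <- km$cluster
      # drop empty clusters, renumber
      ids <- sort(unique(assign_vec))
      assign_vec <- match(assign_vec, ids)
      repeat {
        sizes <- tabulate(assign_vec)
        if (length(sizes) <= 1L || min(sizes) >= stop_at) break
        small <- which.min(sizes)
        members <- assign_vec == small
        others <- setdiff(seq_along(sizes), small)
        if (sizes[small] < delta1) {
          cen_small <- colMeans(xc[members, , drop = FALSE])
          d <- vapply(others, function(o) {
            sqrt(sum((colMeans(xc[assign_vec == o, , drop = FALSE]) -
                        cen_small)^2))
          }, numeric(1))
        } else {
          sig <- median_bandwidth(xc)
          d <- vapply(others, function(o) {
            mmd(xc[members, , drop = FALSE],
                xc[assign_vec == o, , drop = FALSE], sig)
          }, numeric(1))
        }
        target <- others[which.min(d)]
        assign_vec[members] <- target
        ids <- sort(unique(assign_vec))
        assign_vec <- match(assign_vec, ids)
      }
      # canonical domain ids: by first occurrence in canonical row order
      assign_vec <- match(assign_vec, unique(assign_vec))
      k_per_class[ci] <- max(assign_vec)
    }
    out[[ci]] <- data.frame(index = st$index[rows], class = classes[ci],
                            domain = assign_vec)
  }
  part <- do.call(rbind, out)
  part <- part[order(part$index), , drop = FALSE]
  rownames(part) <- NULL
  names(k_per_class) <- as.character(classes)
  structure(part, k_per_class = k_per_class,
            class = c("pg_partition", "data.frame"))
}
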