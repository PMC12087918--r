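#' Slide windows over a feature series
#'
#' With window size `W` and step 1, a series of `T` rows yields exactly
#' `n = T - W + 1` windows; window `i` covers rows `i .. i + W - 1` and takes
#' the label of its last row (the most recent instant).
#'
#' @param fm a `pg_features` from [featurize()].
#' @param window_size window size `W` (number of subseries per sample).
#' @return data frame with one row per window: `index` (= start row),
#'   `last_row`, `label`.
#' @export
slide_windows <- function(fm, window_size) {
  stopifnot(inherits(fm, "pg_features"))
  w <- as.integer(window_size)
  if (w < 2L) stop("window size W must be at least 2", call. = FALSE)
  t_all <- nrow(fm$values)
  if (t_all < w) {
    stop("series has ", t_all, " rows, fewer than one window of size ", w,
         call. = FALSE)
  }
  n <- t_all - w + 1L
  data.frame(index = seq_len(n), last_row = seq_len(n) + w - 1L,
             label = fm$labels[seq_len(n) + w - 1L])
}

#' Window-local min-max rescaling to [-1, 1]
#'
#' `q~_j = (2 q_j - max(Q) - min(Q)) / (max(Q) - min(Q))`. The map is
#' invariant to positive affine transforms of the input, which is what makes
#' a purely local rescaling blind to a window's absolute level; see
#' [rescale_global()] for the complementary series-wide map. A constant
#' window (max = min) is mapped to all zeros, the midpoint of the target
#' interval.
#'
#' @param q numeric vector (one window of one feature column).
#' @return numeric vector in `[-1, 1]`.
#' @export
rescale_local <- function(q) {
  if (length(q) < 2L) stop("window must hold at least 2 values", call. = FALSE)
  lo <- min(q)
  hi <- max(q)
  if (hi == lo) return(rep(0, length(q)))
  (2 * q - hi - lo) / (hi - lo)
}

#' Series-global min-max rescaling to [-1, 1]
#'
#' Same affine map as [rescale_local()] but anchored to the minimum and
#' maximum of the entire (training) series of the feature, so two windows at
#' different absolute levels map to different images and global level
#' information is preserved. Values outside the training range (possible at
#' inference time) are clipped to `[-1, 1]`.
#'
#' @param q numeric vector (one window of one feature column).
#' @param lo,hi feature-wide minimum and maximum from the training series.
#' @return numeric vector in `[-1, 1]`.
#' @export
rescale_global <- function(q, lo, hi) {
  if (hi < lo) stop("scale table entry has max < min", call. = FALSE)
  if (hi == lo) return(rep(0, length(q)))
  pmin(1, pmax(-1, (2 * q - hi - lo) / (hi - lo)))
}

#' Feature-wide min/max table for global rescaling
#'
#' Computed over the given (training) rows only and reused for validation,
#' test and inference windows, so the global anchoring never leaks
#' information from later data.
#'
#' @param fm a `pg_features`.
#' @param rows rows to compute the range over (default: all).
#' @return data frame with `column`, `min`, `max` (class `pg_scale_table`).
#' @export
global_scale_table <- function(fm, rows = seq_len(nrow(fm$values))) {
  x <- fm$values[rows, , drop = FALSE]
  structure(data.frame(column = seq_len(ncol(x)),
                       min = apply(x, 2L, min),
                       max = apply(x, 2L, max)),
            class = c("pg_scale_table", "data.frame"))
}

#' Gramian angular summation field of a rescaled series
#'
#' Maps each rescaled value to a polar angle `phi = arccos(q~)` and returns
#' the `W x W` matrix `G[j, k] = cos(phi_j + phi_k)`, algebraically equal to
#' `q~ q~' - sqrt(1 - q~^2) sqrt(1 - q~^2)'`. `G` is symmetric, bounded in
#' `[-1, 1]`, and its diagonal is `2 q~^2 - 1` (double-angle identity), from
#' which `|q~|` is recoverable. Inputs are clipped to `[-1, 1]` to absorb
#' floating-point overshoot; values further than 1e-9 outside are an error.
#'
#' @param qt numeric vector with values in `[-1, 1]`.
#' @return `W x W` numeric matrix.
#' @export
gasf <- function(qt) {
  q <- clip_unit(qt)
  phi <- acos(q)
  cos(outer(phi, phi, "+"))
}

#' Encode one window as paired local/global GASF stacks
#'
#' For each of the `7 O` feature columns of the window, one local plane
#' (window-local rescaling) and one global plane (series-wide rescaling) are
#' computed and stacked in column (channel-major, then feature) order.
#'
#' @param fm a `pg_features`.
#' @param start first row of the window.
#' @param window_size window size `W`.
#' @param scales a `pg_scale_table` from [global_scale_table()].
#' @return list with `local` and `global` (`W x W x 7O` arrays), `label`,
#'   `index`.
#' @export
encode_window <- function(fm, start, window_size, scales) {
  w <- as.integer(window_size)
  m <- fm$values[start:(start + w - 1L), , drop = FALSE]
  nf <- ncol(m)
  g_local <- array(0, c(w, w, nf))
  g_global <- array(0, c(w, w, nf))
  for (k in seq_len(nf)) {
    g_local[, , k] <- gasf(rescale_local(m[, k]))
    g_global[, , k] <- gasf(rescale_global(m[, k], scales$min[k],
                                           scales$max[k]))
  }
  list(local = g_local, global = g_global,
       label = fm$labels[start + w - 1L], index = start)
}

#' Encode all windows of a feature series for the RBFE
#'
#' Vectorized encoding of every sliding window into the 5-D batch arrays the
#' residual encoder consumes: shape `(1, 7O, W, W, n)` with the feature
#' planes on the depth axis.
#'
#' @param fm a `pg_features` (already z-scored if desired).
#' @param window_size window size `W`.
#' @param scales a `pg_scale_table`; defaults to the full-series table.
#' @param windows optional subset of window start indices.
#' @return list with `x_local`, `x_global` (5-D arrays), `y` (labels),
#'   `index` (window start rows), `layout`.
#' @export
encode_dataset <- function(fm, window_size, scales = global_scale_table(fm),
                           windows = NULL) {
  wins <- slide_windows(fm, window_size)
  if (!is.null(windows)) wins <- wins[wins$index %in% windows, , drop = FALSE]
  w <- as.integer(window_size)
  nf <- ncol(fm$values)
  n <- nrow(wins)
  xl <- array(0, c(1L, nf, w, w, n))
  xg <- array(0, c(1L, nf, w, w, n))
  for (i in seq_len(n)) {
    enc <- encode_window(fm, wins$index[i], w, scales)
    # feature planes become the depth axis: (plane, row, col)
    xl[1L, , , , i] <- aperm(enc$local, c(3L, 1L, 2L))
    xg[1L, , , , i] <- aperm(enc$global, c(3L, 1L, 2L))
  }
  list(x_local = xl, x_global = xg, y = wins$label, index = wins$index,
       layout = fm$layout)
}
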