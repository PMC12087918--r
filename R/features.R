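#' Split a channel into contiguous subseries
#'
#' Divides a uniformly sampled channel into `T = floor(duration /
#' subseries_duration)` contiguous, non-overlapping subseries; a trailing
#' remainder shorter than one subseries is dropped. All channels of a
#' recording share the same duration and therefore yield the same `T`.
#'
#' @param values numeric sample vector.
#' @param sampling_rate samples per second.
#' @param subseries_duration subseries length in seconds.
#' @return list of subseries, each a list with `values`, `sampling_rate`, `n`.
#' @export
split_subseries <- function(values, sampling_rate, subseries_duration = 1) {
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(subseries_duration, "subseries_duration", positive = TRUE)
  n <- as.integer(round(sampling_rate * subseries_duration))
  if (n < 2L) {
    stop("subseries of ", subseries_duration, " s at ", sampling_rate,
         " Hz would hold ", n, " sample(s); at least 2 are required",
         call. = FALSE)
  }
  t_total <- length(values) %/% n
  if (t_total < 1L) stop("channel shorter than one subseries", call. = FALSE)
  lapply(seq_len(t_total), function(t) {
    list(values = values[((t - 1L) * n + 1L):(t * n)],
         sampling_rate = sampling_rate, n = n)
  })
}

#' Time-domain features of a subseries
#'
#' Returns the mean and the sample standard deviation (denominator `N - 1`).
#'
#' @param x numeric vector of at least 2 values.
#' @return named numeric vector `c(x_mean, x_std)`.
#' @export
time_features <- function(x) {
  if (length(x) < 2L) {
    stop("standard deviation undefined for fewer than 2 samples",
         call. = FALSE)
  }
  c(x_mean = mean(x), x_std = sd(x))
}

#' Discrete Fourier transform of a subseries
#'
#' Thin wrapper over the FFT using the conventional bin indexing
#' `j = 0..N-1`, where bin 0 is the DC component. The occasionally seen
#' 1-based convention with `j = 1..N` maps onto this one via `j = N <-> j = 0`
#' (the complex exponential has period `N` in `j`).
#'
#' @param x numeric vector.
#' @return complex vector of length `length(x)`, bin `j` stored at `[j + 1]`.
#' @export
dft <- function(x) {
  if (any(!is.finite(x))) stop("input must be finite", call. = FALSE)
  fft(x)
}

hamming_window <- function(n) {
  if (n < 2L) stop("window needs at least 2 points", call. = FALSE)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

#' Windowed periodogram (power spectral density) of a subseries
#'
#' Computes `P(j) = |sum_k z(k) x_k exp(-i 2 pi j k / N)|^2 / (Z N)` with
#' `Z = mean(z(k)^2)`, a single-segment windowed periodogram. With the
#' rectangular window (`z = 1`, `Z = 1`) this reduces to `|F(j)|^2 / N` and
#' satisfies Parseval's identity `sum_j P(j) = sum_k x_k^2` over all `N`
#' bins. Bins `j = 0..floor(N/2)` (DC up to Nyquist) are retained.
#'
#' @param x numeric sample vector of a subseries.
#' @param sampling_rate samples per second (sets the bin frequencies).
#' @param window `"hamming"` (default, reduces spectral leakage) or `"rect"`.
#' @return object of class `pg_spectrum`: list with `psd`, `bin_freqs` (Hz),
#'   `window`, `Z`, `n`.
#' @export
psd <- function(x, sampling_rate, window = c("hamming", "rect")) {
  window <- match.arg(window)
  n <- length(x)
  if (n < 2L) stop("subseries must hold at least 2 samples", call. = FALSE)
  z <- switch(window, hamming = hamming_window(n), rect = rep(1, n))
  bigz <- mean(z^2)
  f <- fft(z * x)
  keep <- seq_len(n %/% 2L + 1L)
  p <- (Mod(f)^2 / (bigz * n))[keep]
  structure(list(psd = p,
                 bin_freqs = (keep - 1L) * sampling_rate / n,
                 window = window, Z = bigz, n = n),
            class = "pg_spectrum")
}

#' Frequency-domain features of a power spectrum
#'
#' From the retained PSD bins computes: spectral entropy (base-2 Shannon
#' entropy of the normalized PSD, with `0 log 0 := 0`), gravity frequency
#' (PSD-weighted mean bin frequency, i.e. the spectral centroid), frequency
#' mean (the arithmetic mean of the retained PSD values with a `1/N`
#' prefactor, `N` the subseries length -- a power average kept in this form
#' for consistency with the rest of the feature set), frequency standard
#' deviation (PSD-weighted standard deviation of bin frequency around the
#' centroid), and root mean square frequency. The decomposition
#' `x_rmsf^2 = x_fstd^2 + x_gf^2` holds by construction.
#'
#' @param spec a `pg_spectrum` from [psd()].
#' @return named numeric vector
#'   `c(x_se, x_gf, x_fmean, x_fstd, x_rmsf)`.
#' @export
freq_features <- function(spec) {
  stopifnot(inherits(spec, "pg_spectrum"))
  p <- spec$psd
  f <- spec$bin_freqs
  tot <- sum(p)
  if (tot <= 0) stop("degenerate spectrum: all PSD bins are zero",
                     call. = FALSE)
  q <- p / tot
  nz <- q > 0
  x_se <- -sum(q[nz] * log2(q[nz]))
  x_gf <- sum(f * q)
  x_fmean <- tot / spec$n
  x_fstd <- sqrt(max(0, sum((f - x_gf)^2 * q)))
  x_rmsf <- sqrt(sum(f^2 * q))
  c(x_se = x_se, x_gf = x_gf, x_fmean = x_fmean, x_fstd = x_fstd,
    x_rmsf = x_rmsf)
}

.feature_names <- c("mean", "std", "se", "gf", "fmean", "fstd", "rmsf")

#' Pre-extract the feature series of a recording
#'
#' Splits every channel into `T` subseries and computes the 7 features (2
#' time-domain, 5 frequency-domain) per subseries, producing a `T x 7O`
#' feature matrix in chronological order. Column blocks follow the channel
#' order of the recording (channel-major), features within a block in the
#' order mean, std, se, gf, fmean, fstd, rmsf. Each row's label is the label
#' at the end instant of that subseries.
#'
#' @param rec a [raw_recording()].
#' @param cfg a [pipeline_config()] (uses `subseries_duration`, `psd_window`).
#' @return object of class `pg_features`: list with `values` (`T x 7O`
#'   matrix), `labels` (length `T` integer vector), `layout` (data frame
#'   mapping columns to channel/feature), `subseries_duration`.
#' @export
featurize <- function(rec, cfg = pipeline_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  findings <- validate_recording(rec)
  if (any(findings$severity == "error")) {
    stop("recording fails validation: ",
         paste(findings$message[findings$severity == "error"],
               collapse = "; "), call. = FALSE)
  }
  sub_dur <- cfg$subseries_duration
  per_channel <- lapply(rec$channels, function(ch) {
    subs <- split_subseries(ch$samples, ch$spec$sampling_rate, sub_dur)
    t(vapply(subs, function(s) {
      tf <- time_features(s$values)
      ff <- freq_features(psd(s$values, s$sampling_rate,
                              window = cfg$psd_window))
      c(tf, ff)
    }, numeric(7L)))
  })
  t_counts <- vapply(per_channel, nrow, integer(1))
  t_all <- min(t_counts)
  values <- do.call(cbind, lapply(per_channel, function(m)
    m[seq_len(t_all), , drop = FALSE]))
  ch_names <- vapply(rec$channels, function(ch) ch$spec$name, character(1))
  layout <- data.frame(
    column = seq_len(ncol(values)),
    channel = rep(ch_names, each = 7L),
    feature = rep(.feature_names, times = length(ch_names)),
    stringsAsFactors = FALSE)
  colnames(values) <- paste(layout$channel, layout$feature, sep = "_")
  labels <- label_at_times(rec, seq_len(t_all) * sub_dur)
  structure(list(values = values, labels = labels, layout = layout,
                 subseries_duration = sub_dur),
            class = "pg_features")
}

# Label at given instants: label sample k covers [(k-1)/rate, k/rate).
label_at_times <- function(rec, times) {
  idx <- pmin(length(rec$labels), pmax(1L, ceiling(times * rec$label_rate - 1e-9)))
  rec$labels[idx]
}

#' Per-column z-score scaler frozen on a training range
#'
#' Normalization statistics are computed from the given rows only (typically
#' the chronologically earliest, training rows) and then applied to the whole
#' series, so no information from validation or test rows leaks into the
#' scaling.
#'
#' @param fm a `pg_features`.
#' @param rows integer vector of rows to estimate statistics from (default:
#'   all rows).
#' @return list with `center` and `scale` vectors (class `pg_scaler`).
#' @export
feature_scaler <- function(fm, rows = seq_len(nrow(fm$values))) {
  x <- fm$values[rows, , drop = FALSE]
  center <- colMeans(x)
  scale <- apply(x, 2L, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale), class = "pg_scaler")
}

#' Apply a frozen z-score scaler to a feature series
#' @param fm a `pg_features`.
#' @param scaler a `pg_scaler` from [feature_scaler()].
#' @return the `pg_features` with scaled `values`.
#' @export
apply_scaler <- function(fm, scaler) {
  stopifnot(inherits(scaler, "pg_scaler"))
  fm$values <- sweep(sweep(fm$values, 2L, scaler$center), 2L, scaler$scale,
                     "/")
  fm
}
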