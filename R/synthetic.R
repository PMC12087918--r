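#' Specification of a synthetic multichannel recording
#'
#' The generator emulates the statistical structure the pipeline targets,
#' not physiological waveform morphology: each channel is a sinusoid with a
#' class-dependent dominant frequency and amplitude plus Gaussian noise, the
#' class label alternates in contiguous blocks, the baseline and dominant
#' frequency can drift over the recording (temporal covariate shift), and
#' within-class "regimes" (planted domains) shift the parameters in
#' contiguous segments.
#'
#' @param n_classes number of emotion classes C (>= 2).
#' @param n_channels number of channels O.
#' @param duration recording length in seconds.
#' @param sampling_rates per-channel rates in Hz (recycled to O).
#' @param class_freqs C x O matrix of dominant frequencies (Hz); defaults to
#'   well-separated values below every channel's Nyquist frequency.
#' @param amplitudes C x O matrix of amplitudes (default 1).
#' @param baselines length-O baseline levels.
#' @param noise_sd Gaussian noise standard deviation.
#' @param label_block seconds per contiguous class block.
#' @param drift_baseline additive baseline change over the full recording.
#' @param drift_freq relative dominant-frequency change over the full
#'   recording (e.g. 0.5 = +50 %).
#' @param n_regimes number of planted within-class regimes (contiguous
#'   segments of equal length).
#' @param regime_baseline_shift,regime_freq_scale,regime_amp_scale per-regime
#'   parameter offsets (recycled to `n_regimes`; regime 1 is the reference).
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_classes = 2, n_channels = 2, duration = 600,
                       sampling_rates = c(32, 16),
                       class_freqs = NULL, amplitudes = NULL,
                       baselines = NULL, noise_sd = 0.3, label_block = 60,
                       drift_baseline = 0, drift_freq = 0,
                       n_regimes = 1, regime_baseline_shift = 0,
                       regime_freq_scale = 1, regime_amp_scale = 1) {
  stopifnot(n_classes >= 2, n_channels >= 1, duration > 0, n_regimes >= 1)
  sampling_rates <- rep(sampling_rates, length.out = n_channels)
  if (is.null(class_freqs)) {
    base <- seq(1, 6, length.out = n_classes)
    class_freqs <- outer(base, 2^-(seq_len(n_channels) - 1))
  }
  class_freqs <- matrix(class_freqs, n_classes, n_channels)
  if (is.null(amplitudes)) amplitudes <- matrix(1, n_classes, n_channels)
  amplitudes <- matrix(amplitudes, n_classes, n_channels)
  if (is.null(baselines)) baselines <- rep(0, n_channels)
  nyq <- sampling_rates / 2
  max_scale <- max(regime_freq_scale) * (1 + max(0, drift_freq))
  if (any(sweep(class_freqs * max_scale, 2L, nyq, ">="))) {
    stop("a dominant frequency reaches its channel's Nyquist frequency",
         call. = FALSE)
  }
  structure(list(n_classes = as.integer(n_classes),
                 n_channels = as.integer(n_channels), duration = duration,
                 sampling_rates = sampling_rates, class_freqs = class_freqs,
                 amplitudes = amplitudes, baselines = baselines,
                 noise_sd = noise_sd, label_block = label_block,
                 drift_baseline = drift_baseline, drift_freq = drift_freq,
                 n_regimes = as.integer(n_regimes),
                 regime_baseline_shift = rep(regime_baseline_shift,
                                             length.out = n_regimes),
                 regime_freq_scale = rep(regime_freq_scale,
                                         length.out = n_regimes),
                 regime_amp_scale = rep(regime_amp_scale,
                                        length.out = n_regimes)),
            class = "synth_spec")
}

#' Generate a synthetic recording
#'
#' Each channel is `baseline + amplitude * sin(phase(t)) + noise` where the
#' instantaneous frequency is the class's dominant frequency scaled by the
#' active regime and the drift schedule, and the phase is its integral (so
#' drifting frequency produces a clean chirp, not amplitude artifacts).
#' Class labels cycle in contiguous blocks of `label_block` seconds; regimes
#' occupy `n_regimes` contiguous segments of equal length.
#'
#' @param spec a [synth_spec()].
#' @param seed integer seed; generation is deterministic given (spec, seed).
#' @return list with `recording` (a [raw_recording()]), `regime_track`
#'   (regime id per label instant) and `class_track`.
#' @export
generate_recording <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(derive_seed(seed, 23L))
  dur <- spec$duration
  # per-second schedules (label rate is 1 Hz)
  sec <- seq_len(ceiling(dur))
  class_of_sec <- ((ceiling(sec / spec$label_block) - 1L) %%
                     spec$n_classes) + 1L
  regime_of_sec <- pmin(spec$n_regimes,
                        ceiling(sec / (dur / spec$n_regimes)))
  channels <- vector("list", spec$n_channels)
  for (o in seq_len(spec$n_channels)) {
    fs <- spec$sampling_rates[o]
    n <- round(dur * fs)
    tt <- (seq_len(n) - 0.5) / fs
    sec_i <- pmin(length(sec), floor(tt) + 1L)
    cl <- class_of_sec[sec_i]
    rg <- regime_of_sec[sec_i]
    f_inst <- spec$class_freqs[cbind(cl, o)] * spec$regime_freq_scale[rg] *
      (1 + spec$drift_freq * tt / dur)
    phase <- cumsum(2 * pi * f_inst / fs)
    base <- spec$baselines[o] + spec$regime_baseline_shift[rg] +
      spec$drift_baseline * tt / dur
    amp <- spec$amplitudes[cbind(cl, o)] * spec$regime_amp_scale[rg]
    x <- base + amp * sin(phase) + rnorm(n, sd = spec$noise_sd)
    channels[[o]] <- list(spec = channel_spec(paste0("CH", o), fs, "a.u."),
                          samples = x)
  }
  rec <- raw_recording(channels, labels = class_of_sec, label_rate = 1,
                       subject_id = sprintf("SYN%02d", seed %% 100),
                       duration = dur)
  list(recording = rec, regime_track = regime_of_sec,
       class_track = class_of_sec)
}

#' Fixed benchmark bundles
#'
#' Three named study conditions used throughout the test-suite and examples:
#' \describe{
#'   \item{`easy-stationary`}{2 well-separated classes, no drift, one
#'     regime; a small model should learn it almost perfectly.}
#'   \item{`drifting-tcs`}{same classes with baseline and dominant-frequency
#'     drift over the recording plus a mild regime shift at the midpoint --
#'     chronologically later data are distribution-shifted (temporal
#'     covariate shift), and a chronological training span contains planted
#'     within-class domain structure for the alignment loss to work on.}
#'   \item{`two-regime`}{stationary classes but two planted within-class
#'     regimes with shifted baseline/frequency/amplitude, for
#'     domain-segmentation recovery.}
#' }
#'
#' @param name benchmark name (see above).
#' @param seed integer seed.
#' @return list with `recording`, `regime_track`, `class_track`, `spec`, and
#'   `cfg` (a [pipeline_config()] preset with segmentation thresholds scaled
#'   to the bundle's size).
#' @export
generate_benchmark <- function(name = c("easy-stationary", "drifting-tcs",
                                        "two-regime"), seed = 1) {
  name <- match.arg(name)
  spec <- switch(name,
    "easy-stationary" = synth_spec(
      n_classes = 2, n_channels = 2, duration = 840,
      sampling_rates = c(32, 16),
      class_freqs = rbind(c(2, 1), c(6, 4)),
      noise_sd = 0.3, label_block = 60),
    "drifting-tcs" = synth_spec(
      n_classes = 2, n_channels = 2, duration = 1920,
      sampling_rates = c(32, 16),
      class_freqs = rbind(c(2, 1), c(6, 4)),
      noise_sd = 0.2, label_block = 60,
      drift_baseline = 0.5, drift_freq = 0.15,
      n_regimes = 2, regime_amp_scale = c(1, 1.4)),
    "two-regime" = synth_spec(
      n_classes = 2, n_channels = 2, duration = 960,
      sampling_rates = c(32, 16),
      class_freqs = rbind(c(2, 1), c(6, 4)),
      noise_sd = 0.3, label_block = 20,
      n_regimes = 2, regime_baseline_shift = c(0, 3),
      regime_freq_scale = c(1, 1.6), regime_amp_scale = c(1, 1.5)))
  cfg <- switch(name,
    "easy-stationary" = pipeline_config(window_size = 6, batch_size = 128,
                                        n_epochs = 20, lambda = 0,
                                        seed = seed),
    "drifting-tcs" = pipeline_config(window_size = 6, batch_size = 64,
                                     n_epochs = 30, eta = 1e-4,
                                     delta1 = 50, delta2 = 150,
                                     seed = seed),
    "two-regime" = pipeline_config(window_size = 6, batch_size = 128,
                                   delta1 = 50, delta2 = 150, seed = seed))
  out <- generate_recording(spec, seed = seed)
  out$spec <- spec
  out$cfg <- cfg
  out$name <- name
  out
}
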