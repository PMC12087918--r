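#' Channel specification
#'
#' @param name unique channel identifier, e.g. `"EDA"`.
#' @param sampling_rate samples per second (> 0).
#' @param unit free-text physical unit.
#' @return object of class `channel_spec`.
#' @export
channel_spec <- function(name, sampling_rate, unit = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  structure(list(name = name, sampling_rate = sampling_rate, unit = unit),
            class = "channel_spec")
}

#' Multichannel physiological recording
#'
#' Bundles `O >= 1` named channels (each with its own sampling rate) with an
#' aligned per-instant label series. Channel order is preserved exactly as
#' given and determines all downstream feature and image-plane layouts.
#'
#' @param channels list of channels, each a list with `spec` (a
#'   [channel_spec()]) and `samples` (numeric vector).
#' @param labels integer class label per labeled instant.
#' @param label_rate label samples per second.
#' @param subject_id subject identifier.
#' @param duration recording length in seconds; defaults to the duration
#'   implied by the first channel.
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(channels, labels, label_rate = 1,
                          subject_id = "S1", duration = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  for (ch in channels) {
    stopifnot(inherits(ch$spec, "channel_spec"), is.numeric(ch$samples))
  }
  if (is.null(duration)) {
    duration <- length(channels[[1L]]$samples) /
      channels[[1L]]$spec$sampling_rate
  }
  structure(list(channels = channels, labels = as.integer(labels),
                 label_rate = label_rate, subject_id = subject_id,
                 duration = duration),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("Recording '%s': %.1f s, %d channel(s), %d classes\n",
              x$subject_id, x$duration, length(x$channels),
              length(unique(x$labels))))
  for (ch in x$channels) {
    cat(sprintf("  %-8s %6g Hz  %d samples  %s\n", ch$spec$name,
                ch$spec$sampling_rate, length(ch$samples), ch$spec$unit))
  }
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of the full pipeline. Defaults follow the
#' documented presets where the method states them (dropout 0.2, batch size
#' 1024, window size 6, cluster-size thresholds 50/300) and conventional
#' values elsewhere.
#'
#' @param subseries_duration seconds of raw signal per subseries (so the
#'   subseries length is `sampling_rate * subseries_duration` samples).
#' @param window_size sliding-window size `W` in subseries (>= 2).
#' @param learning_rate Adam learning rate.
#' @param lambda weight of the subdomain-alignment (MMD) loss.
#' @param eta weight of the L2 penalty on convolution/linear weights.
#' @param dropout_rate classifier dropout rate.
#' @param batch_size training batch size.
#' @param sigma MMD kernel bandwidth: `"median"` for the median pairwise
#'   distance heuristic, or a positive number.
#' @param delta1,delta2 cluster-size thresholds for domain segmentation
#'   (`delta1 < delta2`): below `delta1` clusters merge by centroid distance,
#'   between the two by MMD; merging continues until the smallest cluster
#'   reaches the stop threshold.
#' @param n_epochs training epochs.
#' @param psd_window window for the periodogram, `"hamming"` or `"rect"`.
#' @param max_gap_seconds longest NaN run repaired by linear interpolation
#'   when reading recordings; longer gaps are an error.
#' @param seed base seed for all stochastic steps.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(subseries_duration = 1, window_size = 6,
                            learning_rate = 1e-3, lambda = 0.01, eta = 1e-6,
                            dropout_rate = 0.2, batch_size = 1024,
                            sigma = "median", delta1 = 50, delta2 = 300,
                            n_epochs = 20, psd_window = "hamming",
                            max_gap_seconds = 0.5, seed = 1) {
  stopifnot_scalar(subseries_duration, "subseries_duration", positive = TRUE)
  if (window_size < 2) stop("window_size W must be >= 2", call. = FALSE)
  if (!(identical(sigma, "median") ||
        (is.numeric(sigma) && length(sigma) == 1L && sigma > 0))) {
    stop("`sigma` must be \"median\" or a positive number", call. = FALSE)
  }
  if (delta1 >= delta2) stop("delta1 must be < delta2", call. = FALSE)
  for (nm in c("learning_rate", "lambda", "eta", "dropout_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0) {
      stop("`", nm, "` must be >= 0", call. = FALSE)
    }
  }
  structure(list(subseries_duration = subseries_duration,
                 window_size = as.integer(window_size),
                 learning_rate = learning_rate, lambda = lambda, eta = eta,
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size), sigma = sigma,
                 delta1 = delta1, delta2 = delta2,
                 n_epochs = as.integer(n_epochs),
                 psd_window = match.arg(psd_window, c("hamming", "rect")),
                 max_gap_seconds = max_gap_seconds,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a recording against its invariants
#'
#' Reporting-only: returns a data frame of findings (empty when all
#' invariants hold) instead of raising errors.
#'
#' @param rec a [raw_recording()].
#' @return data frame with columns `severity`, `location`, `message`.
#' @export
validate_recording <- function(rec) {
  findings <- list()
  note <- function(severity, location, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(severity = severity, location = location, message = message,
                 stringsAsFactors = FALSE)
  }
  nms <- vapply(rec$channels, function(ch) ch$spec$name, character(1))
  if (anyDuplicated(nms)) {
    note("error", "channels", "duplicate channel names")
  }
  for (ch in rec$channels) {
    loc <- paste0("channel ", ch$spec$name)
    if (!is.finite(ch$spec$sampling_rate) || ch$spec$sampling_rate <= 0) {
      note("error", loc, "sampling_rate must be > 0")
      next
    }
    expected <- round(rec$duration * ch$spec$sampling_rate)
    if (abs(length(ch$samples) - expected) > 1) {
      note("error", loc,
           sprintf("%d samples but duration %.3f s at %g Hz implies %d",
                   length(ch$samples), rec$duration, ch$spec$sampling_rate,
                   expected))
    }
    if (any(!is.finite(ch$samples))) {
      note("error", loc, "non-finite samples present")
    }
  }
  label_dur <- length(rec$labels) / rec$label_rate
  if (label_dur < rec$duration - 1 / rec$label_rate) {
    note("error", "labels",
         sprintf("labels cover %.3f s but recording lasts %.3f s",
                 label_dur, rec$duration))
  }
  if (length(findings) == 0L) {
    return(data.frame(severity = character(), location = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

# Linear interpolation over short NaN runs; runs longer than max_gap samples
# are a data error.
fill_gaps <- function(x, max_gap, context = "channel") {
  bad <- !is.finite(x)
  if (!any(bad)) return(x)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    len <- r$lengths[i]
    if (len > max_gap) {
      stop(context, ": gap of ", len, " samples exceeds the configured ",
           "maximum of ", max_gap, call. = FALSE)
    }
    a <- starts[i] - 1L
    b <- ends[i] + 1L
    if (a < 1L || b > length(x)) {
      stop(context, ": non-finite run touches the series boundary",
           call. = FALSE)
    }
    x[starts[i]:ends[i]] <- x[a] + (x[b] - x[a]) *
      seq_len(len) / (len + 1L)
  }
  x
}

#' Write a recording to a directory
#'
#' One CSV per channel plus a label CSV and a YAML manifest naming each
#' channel file and its sampling rate. Samples are printed with 17
#' significant digits so a read/write round trip is bit-exact.
#'
#' @param rec a [raw_recording()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(subject_id = rec$subject_id, duration = rec$duration,
                   labels = list(file = "labels.csv",
                                 sampling_rate = rec$label_rate),
                   channels = lapply(rec$channels, function(ch) {
                     list(name = ch$spec$name,
                          file = paste0(ch$spec$name, ".csv"),
                          sampling_rate = ch$spec$sampling_rate,
                          unit = ch$spec$unit)
                   }))
  for (ch in rec$channels) {
    writeLines(c("value", sprintf("%.17g", ch$samples)),
               file.path(dir, paste0(ch$spec$name, ".csv")))
  }
  writeLines(c("label", as.character(rec$labels)),
             file.path(dir, "labels.csv"))
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a recording from a manifest
#'
#' The manifest (YAML) lists per-channel files and sampling rates, which is
#' how multi-rate recordings are represented without committing to any
#' resampling rule. Short non-finite runs (up to `max_gap_seconds`) are
#' linearly interpolated; longer gaps are a data error.
#'
#' @param manifest_path path to a manifest written by [write_recording()] (or
#'   hand-authored with the same fields).
#' @param max_gap_seconds longest repairable gap, in seconds.
#' @return a [raw_recording()].
#' @export
read_recording <- function(manifest_path, max_gap_seconds = 0.5) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  man <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  for (field in c("subject_id", "duration", "labels", "channels")) {
    if (is.null(man[[field]])) {
      stop("manifest is missing required field `", field, "`", call. = FALSE)
    }
  }
  channels <- lapply(man$channels, function(entry) {
    f <- file.path(dir, entry$file)
    if (!file.exists(f)) {
      stop("channel `", entry$name, "`: file ", entry$file,
           " named in the manifest does not exist", call. = FALSE)
    }
    samples <- read.csv(f)$value
    if (is.null(samples)) {
      stop("channel `", entry$name, "`: column `value` absent from ",
           entry$file, call. = FALSE)
    }
    max_gap <- max(1L, round(max_gap_seconds * entry$sampling_rate))
    samples <- fill_gaps(as.numeric(samples), max_gap,
                         context = paste0("channel ", entry$name))
    list(spec = channel_spec(entry$name, entry$sampling_rate,
                             entry$unit %||% ""),
         samples = samples)
  })
  labf <- file.path(dir, man$labels$file)
  if (!file.exists(labf)) stop("label file not found: ", labf, call. = FALSE)
  labels <- read.csv(labf)$label
  rec <- raw_recording(channels, labels,
                       label_rate = man$labels$sampling_rate,
                       subject_id = man$subject_id, duration = man$duration)
  label_dur <- length(rec$labels) / rec$label_rate
  if (label_dur < rec$duration - 1 / rec$label_rate) {
    stop("labels cover ", label_dur, " s but the recording lasts ",
         rec$duration, " s", call. = FALSE)
  }
  rec
}
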