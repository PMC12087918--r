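#' Fit the full pipeline on a recording
#'
#' Runs every stage end to end: feature pre-extraction, chronological
#' train/validation/test split of the sliding windows, per-column z-scoring
#' and global-scale anchoring frozen on the training rows, GASF encoding,
#' domain segmentation of the training windows (skipped when `lambda = 0`
#' and `segment = FALSE`), RBFE training, and evaluation on each partition.
#'
#' @param rec a [raw_recording()].
#' @param cfg a [pipeline_config()].
#' @param model_cfg an [rbfe_config()]; `num_classes` may be omitted (taken
#'   from the labels).
#' @param ratios chronological split ratios.
#' @param segment force domain segmentation on/off; default on when
#'   `cfg$lambda > 0`.
#' @param verbose print training progress.
#' @return list with `model`, `history`, `report` (train/validation/test
#'   [evaluate_model()] results), `partition`, `split`, `scaler`, `scales`,
#'   `features`.
#' @export
fit_pipeline <- function(rec, cfg = pipeline_config(), model_cfg = NULL,
                         ratios = c(8, 1, 1), segment = cfg$lambda > 0,
                         verbose = FALSE) {
  fm <- featurize(rec, cfg)
  wins <- slide_windows(fm, cfg$window_size)
  split <- chronological_split(wins$index, ratios,
                               window_size = cfg$window_size)
  # freeze normalization and global scaling on rows seen by training windows
  train_rows <- seq_len(max(split$train) + cfg$window_size - 1L)
  scaler <- feature_scaler(fm, train_rows)
  fm_s <- apply_scaler(fm, scaler)
  scales <- global_scale_table(fm_s, train_rows)
  n_classes <- length(unique(fm$labels))
  if (is.null(model_cfg)) {
    model_cfg <- rbfe_config(num_classes = n_classes)
  }
  data <- list(
    train = encode_dataset(fm_s, cfg$window_size, scales, split$train),
    validation = encode_dataset(fm_s, cfg$window_size, scales,
                                split$validation),
    test = encode_dataset(fm_s, cfg$window_size, scales, split$test))
  partition <- NULL
  if (segment) {
    st <- stat_feature_table(fm_s, wins[wins$index %in% split$train, ],
                             cfg$window_size)
    st <- select_relevant(st)
    partition <- segment_domains(st, delta1 = cfg$delta1,
                                 delta2 = cfg$delta2, seed = cfg$seed)
  }
  model <- build_rbfe(model_cfg, input_shape = c(ncol(fm$values),
                                                 cfg$window_size,
                                                 cfg$window_size),
                      seed = derive_seed(cfg$seed, 7L))
  fit <- train_rbfe(model, data$train, partition, cfg, verbose = verbose)
  report <- lapply(data, function(d) evaluate_model(fit$model, d))
  list(model = fit$model, history = fit$history, report = report,
       partition = partition, split = split, scaler = scaler,
       scales = scales, features = fm)
}

#' Per-time-step accuracy under temporal covariate shift
#'
#' Splits the windows into `parts` chronological parts of equal size, trains
#' on the first part only (normalization, global scaling and domain
#' segmentation all frozen on that part) and reports accuracy on parts
#' `2..parts` as time steps `1..parts - 1`. On drifting data the accuracy
#' decays with the time step; on stationary data it should not.
#'
#' @param rec a [raw_recording()].
#' @param cfg a [pipeline_config()].
#' @param model_cfg an [rbfe_config()].
#' @param parts number of chronological parts (default 16).
#' @param segment run domain segmentation on the training part.
#' @return numeric vector of length `parts - 1` with accuracies in percent
#'   (attribute `"train_accuracy"` holds the accuracy on the training part).
#' @export
timestep_eval <- function(rec, cfg = pipeline_config(), model_cfg = NULL,
                          parts = 16, segment = cfg$lambda > 0) {
  fm <- featurize(rec, cfg)
  wins <- slide_windows(fm, cfg$window_size)
  n <- nrow(wins)
  if (n < parts * cfg$window_size) {
    stop("need at least ", parts * cfg$window_size, " windows for ", parts,
         " parts, got ", n, call. = FALSE)
  }
  bounds <- floor(seq_len(parts) * n / parts)
  starts <- c(1L, head(bounds, -1L) + 1L)
  part_idx <- lapply(seq_len(parts), function(p)
    wins$index[starts[p]:bounds[p]])
  train_rows <- seq_len(max(part_idx[[1L]]) + cfg$window_size - 1L)
  scaler <- feature_scaler(fm, train_rows)
  fm_s <- apply_scaler(fm, scaler)
  scales <- global_scale_table(fm_s, train_rows)
  n_classes <- length(unique(fm$labels))
  if (is.null(model_cfg)) {
    model_cfg <- rbfe_config(num_classes = n_classes)
  }
  train_data <- encode_dataset(fm_s, cfg$window_size, scales, part_idx[[1L]])
  partition <- NULL
  if (segment) {
    st <- stat_feature_table(fm_s, wins[wins$index %in% part_idx[[1L]], ],
                             cfg$window_size)
    st <- select_relevant(st)
    partition <- segment_domains(st, delta1 = cfg$delta1,
                                 delta2 = cfg$delta2, seed = cfg$seed)
  }
  model <- build_rbfe(model_cfg, input_shape = c(ncol(fm$values),
                                                 cfg$window_size,
                                                 cfg$window_size),
                      seed = derive_seed(cfg$seed, 7L))
  fit <- train_rbfe(model, train_data, partition, cfg)
  acc <- vapply(2:parts, function(p) {
    d <- encode_dataset(fm_s, cfg$window_size, scales, part_idx[[p]])
    evaluate_model(fit$model, d)$accuracy
  }, numeric(1))
  train_acc <- evaluate_model(fit$model, train_data)$accuracy
  structure(acc, train_accuracy = train_acc)
}
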