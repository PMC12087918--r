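# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Clip values to [-1, 1]; values beyond `tol` outside the interval are an
# error (arccos would be undefined), smaller overshoot is floating-point noise.
clip_unit <- function(x, tol = 1e-9) {
  if (any(x < -1 - tol | x > 1 + tol)) {
    stop("values outside [-1, 1] beyond tolerance ", tol, call. = FALSE)
  }
  pmin(1, pmax(-1, x))
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a finite numeric scalar", call. = FALSE)
  }
  if (positive && x <= 0) stop("`", name, "` must be > 0", call. = FALSE)
  invisible(x)
}

# Flatten all parameter arrays (named w, b, gamma, beta) of a nested model
# list into a flat named list keyed by path, e.g. "streams.local.conv1.w".
# Running batch-norm statistics and structural fields are not parameters.
.param_names <- c("w", "b", "gamma", "beta")

flatten_params <- function(tree, path = character()) {
  out <- list()
  if (!is.list(tree)) return(out)
  nm <- names(tree)
  for (i in seq_along(tree)) {
    key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
    child <- tree[[i]]
    p <- c(path, key)
    if (is.numeric(child) && key %in% .param_names) {
      out[[paste(p, collapse = ".")]] <- child
    } else if (is.list(child)) {
      out <- c(out, flatten_params(child, p))
    }
  }
  out
}

set_param <- function(tree, path_parts, value) {
  key <- path_parts[1L]
  if (grepl("^[0-9]+$", key) && !(key %in% names(tree))) {
    key <- as.integer(key)
  }
  if (length(path_parts) == 1L) {
    dim(value) <- dim(tree[[key]])
    tree[[key]] <- value
    return(tree)
  }
  tree[[key]] <- set_param(tree[[key]], path_parts[-1L], value)
  tree
}

assign_params <- function(model, flat) {
  for (key in names(flat)) {
    model <- set_param(model, strsplit(key, ".", fixed = TRUE)[[1L]], flat[[key]])
  }
  model
}

# Deterministic child seed derived from a base seed (kept below 2^31).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 12289) %% 2147483647)
}
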