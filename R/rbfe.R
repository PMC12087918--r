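#' Configuration for the residual-based feature encoder (RBFE)
#'
#' The RBFE is a dual-stream 3D-convolutional residual network. Each stream
#' processes one of the paired GASF stacks (local or global) through an input
#' layer (3D convolution with a (3,3,3) kernel, batch normalization, ReLU and
#' 3D max pooling), eight residual blocks of which the 3rd, 5th and 7th
#' downsample, global average pooling and a per-stream linear layer. The two
#' stream embeddings are concatenated and fed through dropout into a linear
#' classifier.
#'
#' @param num_classes number of emotion classes C.
#' @param base_width channel count after the input convolution; widths double
#'   at each downsampling block.
#' @param embed_dim output size of each stream's linear layer; the classifier
#'   sees a `2 * embed_dim` concatenated embedding.
#' @param dropout_rate dropout applied between the concatenated embedding and
#'   the classifier.
#' @param n_blocks number of residual blocks per stream.
#' @param downsample_at 1-based indices of the residual blocks that halve the
#'   spatial axes (stride-2 first convolution with a projection skip).
#' @return an object of class `rbfe_config`.
#' @export
rbfe_config <- function(num_classes, base_width = 16, embed_dim = 128,
                        dropout_rate = 0.2, n_blocks = 8,
                        downsample_at = c(3, 5, 7)) {
  stopifnot_scalar(num_classes, "num_classes", positive = TRUE)
  stopifnot_scalar(base_width, "base_width", positive = TRUE)
  stopifnot_scalar(embed_dim, "embed_dim", positive = TRUE)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must be in [0, 1)", call. = FALSE)
  }
  if (any(downsample_at < 1 | downsample_at > n_blocks)) {
    stop("`downsample_at` indices must lie in 1..n_blocks", call. = FALSE)
  }
  structure(list(num_classes = as.integer(num_classes),
                 base_width = as.integer(base_width),
                 embed_dim = as.integer(embed_dim),
                 dropout_rate = dropout_rate,
                 n_blocks = as.integer(n_blocks),
                 downsample_at = as.integer(sort(downsample_at))),
            class = "rbfe_config")
}

conv_out_shape <- function(shape, k, pad, stride) {
  pmax(1L, as.integer((shape + 2L * pad - k) %/% stride + 1L))
}

# Kernel/stride/pad rule for a convolution applied to `shape`: 3-taps with
# padding 1 on axes of size >= 2, 1-tap on collapsed axes; stride 2 only on
# axes that can still shrink (so depth/height/width never fall below 1).
conv_geometry <- function(shape, downsample = FALSE) {
  k <- ifelse(shape >= 2L, 3L, 1L)
  list(k = k, pad = ifelse(k == 3L, 1L, 0L),
       stride = if (downsample) ifelse(shape >= 2L, 2L, 1L) else rep(1L, 3L))
}

make_resblock <- function(cin, cout, downsample, shape) {
  g1 <- conv_geometry(shape, downsample)
  mid <- conv_out_shape(shape, g1$k, g1$pad, g1$stride)
  g2 <- conv_geometry(mid, FALSE)
  block <- list(downsample = downsample,
                conv1 = conv_layer(cin, cout, g1$k, g1$stride, g1$pad),
                bn1 = bn_layer(cout),
                conv2 = conv_layer(cout, cout, g2$k, g2$stride, g2$pad),
                bn2 = bn_layer(cout))
  if (downsample || cin != cout) {
    block$proj <- conv_layer(cin, cout, 1, g1$stride, 0)
    block$bnp <- bn_layer(cout)
  }
  list(block = block, out_shape = mid)
}

build_stream <- function(cfg, input_shape) {
  shape <- as.integer(input_shape)      # (depth, height, width)
  gin <- conv_geometry(shape)
  stream <- list(conv1 = conv_layer(1, cfg$base_width, gin$k, gin$stride,
                                    gin$pad),
                 bn1 = bn_layer(cfg$base_width))
  shape <- conv_out_shape(shape, gin$k, gin$pad, gin$stride)
  shape <- pmax(1L, shape %/% ifelse(shape >= 2L, 2L, 1L))  # max pool
  trace <- list(c(cfg$base_width, shape))
  width <- cfg$base_width
  blocks <- vector("list", cfg$n_blocks)
  for (i in seq_len(cfg$n_blocks)) {
    down <- i %in% cfg$downsample_at
    cout <- if (down) 2L * width else width
    rb <- make_resblock(width, cout, down, shape)
    blocks[[i]] <- rb$block
    shape <- rb$out_shape
    width <- cout
    trace[[i + 1L]] <- c(width, shape)
  }
  stream$blocks <- blocks
  stream$fc <- linear_layer(width, cfg$embed_dim)
  stream$final_width <- width
  stream$shape_trace <- trace
  stream
}

#' Build a dual-stream residual feature encoder
#'
#' @param cfg an [rbfe_config()].
#' @param input_shape integer vector `(depth, height, width)` of one GASF
#'   stack, i.e. `(7 * O, W, W)` for `O` channels and window size `W`.
#' @param seed integer seed for the Kaiming (He) normal initialization.
#' @return an object of class `rbfe_model`.
#' @export
build_rbfe <- function(cfg, input_shape, seed = 1) {
  stopifnot(inherits(cfg, "rbfe_config"), length(input_shape) == 3)
  input_shape <- as.integer(input_shape)
  if (input_shape[2L] < 2L || input_shape[3L] < 2L) {
    stop("window size W must be at least 2 (got ",
         min(input_shape[2:3]), ")", call. = FALSE)
  }
  set.seed(seed)
  model <- list(cfg = cfg, input_shape = input_shape)
  model$streams <- list(local = build_stream(cfg, input_shape),
                        global = build_stream(cfg, input_shape))
  model$cls <- linear_layer(2L * cfg$embed_dim, cfg$num_classes)
  class(model) <- "rbfe_model"
  model
}

resblock_fwd <- function(block, x, training) {
  c1 <- conv_fwd(block$conv1, x)
  b1 <- bn_fwd(block$bn1, c1, training); block$bn1 <- b1$layer
  r1 <- relu_fwd(b1$y)
  c2 <- conv_fwd(block$conv2, r1)
  b2 <- bn_fwd(block$bn2, c2, training); block$bn2 <- b2$layer
  if (!is.null(block$proj)) {
    p <- conv_fwd(block$proj, x)
    bp <- bn_fwd(block$bnp, p, training); block$bnp <- bp$layer
    skip <- bp$y
  } else {
    p <- NULL; bp <- NULL; skip <- x
  }
  s <- b2$y + skip
  y <- relu_fwd(s)
  list(y = y, block = block,
       cache = list(x = x, bn1 = b1$cache, r1 = r1, bn2 = b2$cache,
                    bnp = if (!is.null(bp)) bp$cache, y = y))
}

resblock_bwd <- function(block, cache, dy) {
  ds <- relu_bwd(cache$y, dy)
  g <- list()
  bb2 <- bn_bwd(block$bn2, cache$bn2, ds)
  g$bn2 <- list(gamma = bb2$dgamma, beta = bb2$dbeta)
  cb2 <- conv_bwd(block$conv2, cache$r1, bb2$dx)
  g$conv2 <- list(w = cb2$dw)
  dr1 <- relu_bwd(cache$r1, cb2$dx)
  bb1 <- bn_bwd(block$bn1, cache$bn1, dr1)
  g$bn1 <- list(gamma = bb1$dgamma, beta = bb1$dbeta)
  cb1 <- conv_bwd(block$conv1, cache$x, bb1$dx)
  g$conv1 <- list(w = cb1$dw)
  dx <- cb1$dx
  if (!is.null(block$proj)) {
    bbp <- bn_bwd(block$bnp, cache$bnp, ds)
    g$bnp <- list(gamma = bbp$dgamma, beta = bbp$dbeta)
    cbp <- conv_bwd(block$proj, cache$x, bbp$dx)
    g$proj <- list(w = cbp$dw)
    dx <- dx + cbp$dx
  } else {
    dx <- dx + ds
  }
  list(dx = dx, grads = g)
}

stream_fwd <- function(stream, x, training) {
  c1 <- conv_fwd(stream$conv1, x)
  b1 <- bn_fwd(stream$bn1, c1, training); stream$bn1 <- b1$layer
  r1 <- relu_fwd(b1$y)
  pl <- pool_fwd(r1)
  h <- pl$y
  bcaches <- vector("list", length(stream$blocks))
  for (i in seq_along(stream$blocks)) {
    res <- resblock_fwd(stream$blocks[[i]], h, training)
    stream$blocks[[i]] <- res$block
    bcaches[[i]] <- res$cache
    h <- res$y
  }
  gp <- gpool_fwd(h)
  embed <- linear_fwd(stream$fc, gp$y)
  list(embed = embed, stream = stream,
       cache = list(x = x, bn1 = b1$cache, r1 = r1, pool = pl,
                    blocks = bcaches, gp = gp, gpy = gp$y))
}

stream_bwd <- function(stream, cache, dembed) {
  g <- list()
  lb <- linear_bwd(stream$fc, cache$gpy, dembed)
  g$fc <- list(w = lb$dw, b = lb$db)
  dh <- gpool_bwd(cache$gp, lb$dx)
  g$blocks <- vector("list", length(stream$blocks))
  for (i in rev(seq_along(stream$blocks))) {
    rb <- resblock_bwd(stream$blocks[[i]], cache$blocks[[i]], dh)
    g$blocks[[i]] <- rb$grads
    dh <- rb$dx
  }
  dr1 <- pool_bwd(cache$pool, dh)
  dr1 <- relu_bwd(cache$r1, dr1)
  bb1 <- bn_bwd(stream$bn1, cache$bn1, dr1)
  g$bn1 <- list(gamma = bb1$dgamma, beta = bb1$dbeta)
  cb1 <- conv_bwd(stream$conv1, cache$x, bb1$dx)
  g$conv1 <- list(w = cb1$dw)
  g
}

#' Forward pass of the RBFE
#'
#' @param model an [build_rbfe()] model.
#' @param x_local,x_global arrays of shape `(1, depth, W, W, N)` holding the
#'   local and global GASF stacks of a batch, as produced by
#'   [encode_dataset()].
#' @param training logical; training mode uses batch statistics and dropout,
#'   evaluation mode is deterministic.
#' @param keep_cache keep intermediate activations for a backward pass.
#' @return list with `logits` (C x N), `embedding` (2*embed_dim x N, the exact
#'   input to the classifier before dropout), the updated `model`, and
#'   (optionally) `cache`.
#' @export
rbfe_forward <- function(model, x_local, x_global, training = FALSE,
                         keep_cache = FALSE) {
  for (x in list(x_local, x_global)) {
    d <- dim(x)
    if (length(d) != 5L || d[1L] != 1L ||
        !all(d[2:4] == model$input_shape)) {
      stop("input shape (", paste(d, collapse = ", "),
           ") does not match the model's build-time channels/shape (1, ",
           paste(model$input_shape, collapse = ", "), ", N)", call. = FALSE)
    }
  }
  sl <- stream_fwd(model$streams$local, x_local, training)
  sg <- stream_fwd(model$streams$global, x_global, training)
  model$streams$local <- sl$stream
  model$streams$global <- sg$stream
  embed <- rbind(sl$embed, sg$embed)
  dp <- dropout_fwd(embed, model$cfg$dropout_rate, training)
  logits <- linear_fwd(model$cls, dp$y)
  out <- list(logits = logits, embedding = embed, model = model)
  if (keep_cache) {
    out$cache <- list(local = sl$cache, global = sg$cache,
                      dropout = dp, dpy = dp$y)
  }
  out
}

# Backward pass: dlogits is C x N; dembed_extra (2E x N, optional) is an
# additional gradient applied directly to the pre-dropout embedding (used by
# the subdomain-alignment loss). Returns flat named gradients.
rbfe_backward <- function(model, cache, dlogits, dembed_extra = NULL) {
  g <- list()
  lb <- linear_bwd(model$cls, cache$dpy, dlogits)
  g$cls <- list(w = lb$dw, b = lb$db)
  dembed <- dropout_bwd(cache$dropout, lb$dx)
  if (!is.null(dembed_extra)) dembed <- dembed + dembed_extra
  e <- model$cfg$embed_dim
  g$streams <- list(
    local = stream_bwd(model$streams$local, cache$local,
                       dembed[seq_len(e), , drop = FALSE]),
    global = stream_bwd(model$streams$global, cache$global,
                        dembed[e + seq_len(e), , drop = FALSE]))
  flatten_params(g)
}

#' Number of trainable parameters of an RBFE model
#' @param model an `rbfe_model`.
#' @return integer parameter count.
#' @export
rbfe_param_count <- function(model) {
  sum(vapply(flatten_params(model), length, integer(1)))
}

#' @export
print.rbfe_model <- function(x, ...) {
  cfg <- x$cfg
  cat("Dual-stream residual feature encoder\n")
  cat(sprintf("  input stack: (%s)  [depth, W, W]\n",
              paste(x$input_shape, collapse = ", ")))
  cat(sprintf("  base width %d, %d residual blocks (downsampling at %s)\n",
              cfg$base_width, cfg$n_blocks,
              paste(cfg$downsample_at, collapse = ", ")))
  tr <- x$streams$local$shape_trace
  for (i in seq_along(tr)) {
    lbl <- if (i == 1) "input layer" else sprintf("block %d", i - 1L)
    cat(sprintf("    %-12s -> channels %3d, spatial (%s)\n", lbl,
                tr[[i]][1L], paste(tr[[i]][-1L], collapse = ", ")))
  }
  cat(sprintf("  per-stream embedding %d, classifier %d -> %d classes\n",
              cfg$embed_dim, 2L * cfg$embed_dim, cfg$num_classes))
  cat(sprintf("  trainable parameters: %s\n",
              format(rbfe_param_count(x), big.mark = ",")))
  invisible(x)
}
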