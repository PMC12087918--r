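tiny_cfg <- function(...) {
  rbfe_config(num_classes = 3, base_width = 2, embed_dim = 4,
              dropout_rate = 0, ...)
}

tiny_batch <- function(n = 4, depth = 7, w = 4, seed = 1) {
  set.seed(seed)
  list(xl = array(rnorm(depth * w * w * n), c(1, depth, w, w, n)),
       xg = array(rnorm(depth * w * w * n), c(1, depth, w, w, n)),
       y = rep_len(1:3, n))
}

test_that("model structure follows the configuration contracts", {
  cfg <- rbfe_config(num_classes = 4, base_width = 16, embed_dim = 128)
  model <- build_rbfe(cfg, c(14, 6, 6), seed = 1)
  # classifier consumes the concatenation of both stream embeddings
  expect_identical(dim(model$cls$w), c(4L, 256L))
  expect_identical(length(model$streams$local$blocks), 8L)
  expect_error(build_rbfe(cfg, c(14, 1, 1)), "W must be at least 2")
})

test_that("downsampling blocks halve spatial axes and double channels", {
  cfg <- rbfe_config(num_classes = 2, base_width = 8, embed_dim = 16)
  model <- build_rbfe(cfg, c(7, 16, 16), seed = 1)
  tr <- model$streams$local$shape_trace
  # input layer: (7,16,16) -> conv same -> pool -> (3,8,8) at 8 channels
  expect_identical(tr[[1]], c(8L, 3L, 8L, 8L))
  # block 2 (no downsampling) preserves dims
  expect_identical(tr[[3]], tr[[2]])
  # block 3 downsamples: spatial halved (ceil), channels doubled
  expect_identical(tr[[4]], c(16L, 2L, 4L, 4L))
  expect_identical(tr[[6]], c(32L, 1L, 2L, 2L))
  expect_identical(tr[[8]], c(64L, 1L, 1L, 1L))
})

test_that("parameter count matches the hand-computed total for a small config", {
  model <- build_rbfe(tiny_cfg(), c(7, 4, 4), seed = 1)
  # Hand count for base_width 2, embed 4, C = 3, input (7,4,4).
  # Shapes: input layer -> (2 ch, 3,2,2); blocks 1-2 at (3,2,2);
  # block 3 ds -> (4 ch, 2,1,1); block 4 same; block 5 ds -> (8 ch, 1,1,1);
  # blocks 6-8 at (1,1,1) with 1-tap kernels on collapsed axes.
  # stream: conv1 54 + bn1 4 + blocks (224,224,296,112,240,160,608,576)
  #         + fc 68 = 2566; two streams 5132; classifier 3x8 + 3 = 27.
  expect_identical(rbfe_param_count(model), 5159L)
})

test_that("forward pass shapes, stream independence and determinism", {
  model <- build_rbfe(tiny_cfg(), c(7, 4, 4), seed = 2)
  b <- tiny_batch(n = 3)
  out <- rbfe_forward(model, b$xl, b$xg)
  expect_identical(dim(out$logits), c(3L, 3L))
  expect_identical(dim(out$embedding), c(8L, 3L))
  # evaluation mode is bit-deterministic
  out2 <- rbfe_forward(model, b$xl, b$xg)
  expect_identical(out$logits, out2$logits)
  # the two streams have independent weights: swapping inputs changes output
  out3 <- rbfe_forward(model, b$xg, b$xl)
  expect_gt(max(abs(out3$logits - out$logits)), 1e-8)
  # shape mismatch errors
  expect_error(rbfe_forward(model, b$xl[, 1:5, , , , drop = FALSE], b$xg),
               "channels")
})

test_that("a zero-weight non-downsampling block is the identity under ReLU", {
  model <- build_rbfe(tiny_cfg(), c(7, 4, 4), seed = 3)
  blk <- model$streams$local$blocks[[1]]
  blk$conv1$w[] <- 0
  blk$conv2$w[] <- 0
  x <- abs(array(rnorm(2 * 3 * 2 * 2 * 5), c(2, 3, 2, 2, 5)))  # post-ReLU
  out <- physiogasf:::resblock_fwd(blk, x, training = FALSE)
  expect_equal(out$y, x, tolerance = 1e-12)
})

test_that("every parameter receives gradient on a random batch", {
  model <- build_rbfe(tiny_cfg(), c(7, 4, 4), seed = 4)
  b <- tiny_batch(n = 16, seed = 5)
  fw <- rbfe_forward(model, b$xl, b$xg, training = TRUE, keep_cache = TRUE)
  probs <- physiogasf:::softmax_cols(fw$logits)
  dlogits <- probs
  dlogits[cbind(b$y, seq_along(b$y))] <-
    dlogits[cbind(b$y, seq_along(b$y))] - 1
  grads <- physiogasf:::rbfe_backward(model, fw$cache, dlogits / 16)
  expect_setequal(names(grads),
                  names(physiogasf:::flatten_params(model)))
  nonzero <- vapply(grads, function(g) any(g != 0), logical(1))
  expect_true(all(nonzero))
})

test_that("analytic gradients agree with central differences", {
  model <- build_rbfe(tiny_cfg(), c(5, 4, 4), seed = 6)
  b <- tiny_batch(n = 3, depth = 5, seed = 7)
  loss_of <- function(m) {
    fw <- rbfe_forward(m, b$xl, b$xg, training = TRUE, keep_cache = TRUE)
    p <- physiogasf:::softmax_cols(fw$logits)
    list(loss = -mean(log(p[cbind(b$y, 1:3)])), fw = fw, p = p)
  }
  res <- loss_of(model)
  dlogits <- res$p
  dlogits[cbind(b$y, 1:3)] <- dlogits[cbind(b$y, 1:3)] - 1
  grads <- physiogasf:::rbfe_backward(model, res$fw$cache, dlogits / 3)
  flat <- physiogasf:::flatten_params(model)
  eps <- 1e-5
  set.seed(8)
  for (key in sample(names(flat), 12)) {
    i <- sample(length(flat[[key]]), 1)
    for (sgn in c(1, -1)) {
      pert <- flat
      pert[[key]][i] <- pert[[key]][i] + sgn * eps
      assign(if (sgn > 0) "lp" else "lm",
             loss_of(physiogasf:::assign_params(model, pert[key]))$loss)
    }
    num <- (lp - lm) / (2 * eps)
    expect_equal(grads[[key]][i], num, tolerance = 1e-4,
                 label = paste("grad", key))
  }
})

test_that("conv3d forward matches a naive R convolution", {
  naive_conv <- function(x, w, stride, pad) {
    d <- dim(x); wd <- dim(w)
    k <- wd[3:5]
    outd <- pmax(1, (d[2:4] + 2 * pad - k) %/% stride + 1)
    y <- array(0, c(wd[1], outd, d[5]))
    for (n in seq_len(d[5])) for (co in seq_len(wd[1]))
      for (od in 1:outd[1]) for (oh in 1:outd[2]) for (ow in 1:outd[3]) {
        acc <- 0
        for (ci in seq_len(d[1])) for (kd in 1:k[1]) for (kh in 1:k[2])
          for (kw in 1:k[3]) {
            dd <- (od - 1) * stride[1] - pad[1] + kd
            hh <- (oh - 1) * stride[2] - pad[2] + kh
            ww <- (ow - 1) * stride[3] - pad[3] + kw
            if (dd >= 1 && dd <= d[2] && hh >= 1 && hh <= d[3] &&
                ww >= 1 && ww <= d[4]) {
              acc <- acc + x[ci, dd, hh, ww, n] * w[co, ci, kd, kh, kw]
            }
          }
        y[co, od, oh, ow, n] <- acc
      }
    y
  }
  set.seed(9)
  x <- array(rnorm(2 * 4 * 5 * 3 * 2), c(2, 4, 5, 3, 2))
  for (stride in list(c(1L, 1L, 1L), c(2L, 2L, 1L))) {
    w <- array(rnorm(3 * 2 * 3 * 3 * 1), c(3, 2, 3, 3, 1))
    y <- physiogasf:::conv3d_forward_cpp(x, w, numeric(3), stride,
                                         c(1L, 1L, 0L))
    expect_equal(as.numeric(y),
                 as.numeric(naive_conv(x, w, stride, c(1, 1, 0))),
                 tolerance = 1e-12)
  }
})
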