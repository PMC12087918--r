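#' Cross-entropy classification loss
#'
#' `-(1/N) sum_i log p_i(y_i)` over the true-class predicted probabilities,
#' natural logarithm, with a floor of 1e-12 inside the log.
#'
#' @param pred_probs `N x C` matrix of predicted class probabilities; rows
#'   must sum to 1 within 1e-6.
#' @param labels integer class labels in `1..C`.
#' @return nonnegative scalar.
#' @export
cross_entropy <- function(pred_probs, labels) {
  if (!is.matrix(pred_probs)) pred_probs <- matrix(pred_probs, nrow = 1L)
  if (any(abs(rowSums(pred_probs) - 1) > 1e-6)) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > ncol(pred_probs))) {
    stop("labels out of range", call. = FALSE)
  }
  -mean(log(pmax(pred_probs[cbind(seq_along(labels), labels)], 1e-12)))
}

#' Subdomain-alignment distance loss
#'
#' For every class present with at least two represented domains, the MMD
#' distances over all unordered domain pairs are averaged; the loss is the
#' mean of these per-class values. Classes with fewer than two represented
#' domains contribute nothing; the loss is 0 when no class has a pair.
#'
#' @param embeddings `p x N` matrix of per-sample embeddings (columns are
#'   samples, matching the model's embedding output).
#' @param labels integer class per sample.
#' @param domains integer domain id per sample.
#' @param sigma MMD kernel bandwidth.
#' @return nonnegative scalar.
#' @export
distance_loss <- function(embeddings, labels, domains, sigma) {
  distance_loss_grad(embeddings, labels, domains, sigma,
                     want_grad = FALSE)$loss
}

# Loss and (optionally) gradient with respect to the embedding matrix.
distance_loss_grad <- function(embeddings, labels, domains, sigma,
                               want_grad = TRUE) {
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  e <- t(embeddings)                      # samples x p
  n <- nrow(e)
  grad <- if (want_grad) matrix(0, n, ncol(e)) else NULL
  per_class <- numeric(0)
  class_grads <- list()
  for (cl in sort(unique(labels))) {
    doms <- sort(unique(domains[labels == cl]))
    doms <- doms[vapply(doms, function(d)
      sum(labels == cl & domains == d) > 0, logical(1))]
    if (length(doms) < 2L) next
    pairs <- utils::combn(doms, 2L)
    acc <- 0
    gacc <- if (want_grad) matrix(0, n, ncol(e)) else NULL
    for (p in seq_len(ncol(pairs))) {
      iu <- which(labels == cl & domains == pairs[1L, p])
      iv <- which(labels == cl & domains == pairs[2L, p])
      u <- e[iu, , drop = FALSE]
      v <- e[iv, , drop = FALSE]
      acc <- acc + mmd(u, v, sigma)
      if (want_grad) {
        g <- mmd_grad(u, v, sigma)
        gacc[iu, ] <- gacc[iu, ] + g$du
        gacc[iv, ] <- gacc[iv, ] + g$dv
      }
    }
    per_class <- c(per_class, acc / ncol(pairs))
    if (want_grad) class_grads[[length(per_class)]] <- gacc / ncol(pairs)
  }
  if (length(per_class) == 0L) {
    return(list(loss = 0, grad = if (want_grad) t(grad)))
  }
  loss <- mean(per_class)
  if (want_grad) {
    for (g in class_grads) grad <- grad + g / length(per_class)
    return(list(loss = loss, grad = t(grad)))
  }
  list(loss = loss, grad = NULL)
}

# Gradient of mmd(U, V, sigma) with respect to the rows of U and V.
mmd_grad <- function(u, v, sigma) {
  a <- nrow(u)
  b <- nrow(v)
  s2 <- sigma^2
  kmat <- function(x, y) {
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
    exp(-pmax(d2, 0) / (2 * s2))
  }
  kuu <- kmat(u, u)
  kvv <- kmat(v, v)
  kuv <- kmat(u, v)
  # d/du_i mean(kuu): -(2/(a^2 s2)) sum_j kuu_ij (u_i - u_j)
  du <- -(2 / (a^2 * s2)) * (rowSums(kuu) * u - kuu %*% u) +
    (2 / (a * b * s2)) * (rowSums(kuv) * u - kuv %*% v)
  dv <- -(2 / (b^2 * s2)) * (rowSums(kvv) * v - kvv %*% v) +
    (2 / (a * b * s2)) * (colSums(kuv) * v - t(kuv) %*% u)
  list(du = du, dv = dv)
}

#' L2 penalty on model weights
#'
#' Sum of squared entries of all convolution and linear weight tensors;
#' biases and batch-normalization parameters are excluded.
#'
#' @param model an `rbfe_model`.
#' @return nonnegative scalar.
#' @export
l2_penalty <- function(model) {
  flat <- flatten_params(model)
  sum(vapply(flat[grepl("\\.w$", names(flat))],
             function(w) sum(w^2), numeric(1)))
}

#' Domain-stratified batch order
#'
#' Produces an epoch ordering in which consecutive samples cycle round-robin
#' over the (class, domain) cells, so any batch of at least the number of
#' cells contains two or more domains of some class whenever the partition
#' has them -- the alignment loss then always sees non-degenerate pairs.
#' Every sample appears exactly once per epoch; deterministic under `seed`.
#'
#' @param labels integer class per training sample.
#' @param domains integer domain per training sample.
#' @param batch_size batch size.
#' @param seed integer seed.
#' @return list of integer index vectors, one per batch.
#' @export
make_batches <- function(labels, domains, batch_size, seed = 1) {
  n <- length(labels)
  set.seed(derive_seed(seed, 17L))
  cell <- paste(labels, domains, sep = "/")
  groups <- split(seq_len(n), cell)
  groups <- lapply(groups, function(g) g[sample.int(length(g))])
  groups <- groups[order(-lengths(groups))]
  order_vec <- integer(n)
  pos <- 1L
  ptr <- rep(1L, length(groups))
  while (pos <= n) {
    for (gi in seq_along(groups)) {
      if (ptr[gi] <= length(groups[[gi]])) {
        order_vec[pos] <- groups[[gi]][ptr[gi]]
        ptr[gi] <- ptr[gi] + 1L
        pos <- pos + 1L
      }
    }
  }
  split(order_vec, ceiling(seq_len(n) / batch_size))
}

softmax_cols <- function(logits) {
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  sweep(e, 2L, colSums(e), "/")
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (key in names(flat)) {
    g <- grads[[key]]
    if (is.null(g)) next
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    flat[[key]] <- flat[[key]] -
      lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

#' Train an RBFE with classification, alignment and L2 losses
#'
#' Minimizes `L = L_cls + lambda * L_dis + eta * ||W||^2` with Adam. `L_cls`
#' is the softmax cross-entropy of the classifier, `L_dis` the
#' subdomain-alignment MMD loss on the pre-classifier embeddings (batch-wise,
#' over the domains present in each batch), and `||W||^2` the L2 penalty of
#' [l2_penalty()]. With `lambda = 0` and `eta = 0` this reduces exactly to
#' plain cross-entropy training.
#'
#' @param model an `rbfe_model` from [build_rbfe()].
#' @param data encoded dataset from [encode_dataset()] (training samples).
#' @param partition a `pg_partition` from [segment_domains()], or `NULL` for
#'   a single domain per class.
#' @param cfg a [pipeline_config()]; uses `learning_rate`, `lambda`, `eta`,
#'   `batch_size`, `n_epochs`, `sigma`, `seed`.
#' @param verbose print a line per epoch.
#' @return list with the trained `model` and `history`, a data frame with one
#'   row per optimization step holding `l_cls`, `l_dis`, `l_reg`, `l_total`,
#'   `lambda`, `eta`.
#' @export
train_rbfe <- function(model, data, partition = NULL,
                       cfg = pipeline_config(), verbose = FALSE) {
  y <- as.integer(data$y)
  n <- length(y)
  stopifnot(n >= 2L, max(y) <= model$cfg$num_classes)
  domains <- rep(1L, n)
  if (!is.null(partition)) {
    m <- match(data$index, partition$index)
    if (any(is.na(m))) {
      stop("partition does not cover every training sample", call. = FALSE)
    }
    domains <- partition$domain[m]
  }
  lambda <- cfg$lambda
  eta <- cfg$eta
  flat <- flatten_params(model)
  state <- adam_init(flat)
  history <- vector("list", 0L)
  for (epoch in seq_len(cfg$n_epochs)) {
    batches <- make_batches(y, domains, cfg$batch_size,
                            seed = derive_seed(cfg$seed, epoch))
    set.seed(derive_seed(cfg$seed, 100000L + epoch))  # dropout masks
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      xl <- data$x_local[, , , , idx, drop = FALSE]
      xg <- data$x_global[, , , , idx, drop = FALSE]
      yb <- y[idx]
      fw <- rbfe_forward(model, xl, xg, training = TRUE, keep_cache = TRUE)
      model <- fw$model
      probs <- softmax_cols(fw$logits)
      l_cls <- -mean(log(pmax(probs[cbind(yb, seq_along(idx))], 1e-12)))
      dlogits <- probs
      dlogits[cbind(yb, seq_along(idx))] <-
        dlogits[cbind(yb, seq_along(idx))] - 1
      dlogits <- dlogits / length(idx)
      l_dis <- 0
      dembed <- NULL
      if (lambda > 0) {
        sig <- if (identical(cfg$sigma, "median")) {
          median_bandwidth(t(fw$embedding))
        } else cfg$sigma
        dl <- distance_loss_grad(fw$embedding, yb, domains[idx], sig)
        l_dis <- dl$loss
        if (!is.null(dl$grad) && l_dis > 0) dembed <- lambda * dl$grad
      }
      grads <- rbfe_backward(model, fw$cache, dlogits, dembed)
      l_reg <- l2_penalty(model)
      if (eta > 0) {
        for (key in names(grads)) {
          if (grepl("\\.w$", key)) {
            grads[[key]] <- grads[[key]] + 2 * eta * flat[[key]]
          }
        }
      }
      flat <- flatten_params(model)
      upd <- adam_step(flat, grads, state, cfg$learning_rate)
      flat <- upd$flat
      state <- upd$state
      model <- assign_params(model, flat)
      l_total <- l_cls + lambda * l_dis + eta * l_reg
      if (!is.finite(l_total)) {
        stop("non-finite loss at epoch ", epoch, ", batch ", bi,
             " (l_cls = ", l_cls, ", l_dis = ", l_dis, ")", call. = FALSE)
      }
      history[[length(history) + 1L]] <-
        data.frame(epoch = epoch, batch = bi, l_cls = l_cls, l_dis = l_dis,
                   l_reg = l_reg, l_total = l_total, lambda = lambda,
                   eta = eta)
    }
    if (verbose) {
      last <- history[[length(history)]]
      message(sprintf("epoch %3d  l_cls %.4f  l_dis %.4f  l_reg %.2f",
                      epoch, last$l_cls, last$l_dis, last$l_reg))
    }
  }
  model <- bn_recalibrate(model, data)
  list(model = model, history = do.call(rbind, history))
}

# Replace batch-norm running statistics with population statistics estimated
# over the training set. Statistics accumulated step by step during training
# lag the final weights (each was computed under earlier parameters), which
# distorts deterministic evaluation-mode forwards; a final pass under the
# trained weights removes the mismatch. Chunks are averaged with momentum
# 1/i, i.e. equal weight per chunk.
bn_recalibrate <- function(model, data, chunk_size = 256L) {
  n <- length(data$y)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
  set_momentum <- function(m, value) {
    m$streams <- lapply(m$streams, function(s) {
      s$bn1$momentum <- value
      s$blocks <- lapply(s$blocks, function(b) {
        for (nm in c("bn1", "bn2", "bnp")) {
          if (!is.null(b[[nm]])) b[[nm]]$momentum <- value
        }
        b
      })
      s
    })
    m
  }
  for (i in seq_along(chunks)) {
    model <- set_momentum(model, 1 / i)
    idx <- chunks[[i]]
    fw <- rbfe_forward(model,
                       data$x_local[, , , , idx, drop = FALSE],
                       data$x_global[, , , , idx, drop = FALSE],
                       training = TRUE)
    model <- fw$model
  }
  set_momentum(model, 0.1)
}

#' Chronological train/validation/test split
#'
#' Samples are ordered by their chronological index; the earliest fraction
#' goes to training, the next to validation, the last to test (default
#' 8:1:1). Validation and test sizes are floored, the remainder goes to
#' training. Because windows overlap (step 1), windows near a boundary share
#' feature rows with the neighbouring partition; these are flagged in the
#' `"boundary_overlap"` attribute rather than silently dropped.
#'
#' @param index chronological window indices (start rows).
#' @param ratios length-3 positive weights.
#' @param window_size window size `W` used to flag boundary-overlap windows.
#' @return list with integer index vectors `train`, `validation`, `test`.
#' @export
chronological_split <- function(index, ratios = c(8, 1, 1), window_size = 1) {
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  ord <- order(index)
  n <- length(index)
  n_val <- floor(n * ratios[2L] / sum(ratios))
  n_test <- floor(n * ratios[3L] / sum(ratios))
  n_train <- n - n_val - n_test
  if (min(n_train, n_val, n_test) < 1L) {
    stop("too few samples (", n, ") for three non-empty partitions",
         call. = FALSE)
  }
  parts <- list(train = index[ord[seq_len(n_train)]],
                validation = index[ord[n_train + seq_len(n_val)]],
                test = index[ord[n_train + n_val + seq_len(n_test)]])
  overlap <- c(
    sum(parts$validation < max(parts$train) + window_size),
    sum(parts$test < max(parts$validation) + window_size))
  attr(parts, "boundary_overlap") <-
    c(validation = overlap[1L], test = overlap[2L])
  parts
}

#' Evaluate a trained model
#'
#' @param model a trained `rbfe_model`.
#' @param data encoded dataset from [encode_dataset()].
#' @param f1 `"macro"` (default) or `"weighted"`.
#' @param chunk_size forward-pass batch size.
#' @return object of class `pg_eval`: list with `accuracy` and `f1` (both in
#'   percent), `confusion` (C x C matrix, rows = true class), `predicted`.
#' @export
evaluate_model <- function(model, data, f1 = c("macro", "weighted"),
                           chunk_size = 256L) {
  f1 <- match.arg(f1)
  y <- as.integer(data$y)
  n <- length(y)
  if (n == 0L) stop("empty sample set", call. = FALSE)
  pred <- integer(n)
  for (lo in seq(1L, n, by = chunk_size)) {
    hi <- min(n, lo + chunk_size - 1L)
    fw <- rbfe_forward(model,
                       data$x_local[, , , , lo:hi, drop = FALSE],
                       data$x_global[, , , , lo:hi, drop = FALSE],
                       training = FALSE)
    pred[lo:hi] <- apply(fw$logits, 2L, which.max)
  }
  classification_report(pred, y, model$cfg$num_classes, f1)
}

# Accuracy, per-class F1 aggregate and confusion matrix from label vectors.
classification_report <- function(pred, y, c_classes, f1 = "macro") {
  n <- length(y)
  confusion <- matrix(0L, c_classes, c_classes,
                      dimnames = list(true = seq_len(c_classes),
                                      predicted = seq_len(c_classes)))
  for (i in seq_len(n)) {
    confusion[y[i], pred[i]] <- confusion[y[i], pred[i]] + 1L
  }
  acc <- 100 * sum(diag(confusion)) / n
  per_class_f1 <- vapply(seq_len(c_classes), function(c) {
    tp <- confusion[c, c]
    fp <- sum(confusion[, c]) - tp
    fn <- sum(confusion[c, ]) - tp
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  present <- rowSums(confusion) > 0
  f1_val <- if (f1 == "macro") {
    100 * mean(per_class_f1[present])
  } else {
    100 * sum(per_class_f1[present] * rowSums(confusion)[present]) / n
  }
  structure(list(accuracy = acc, f1 = f1_val, confusion = confusion,
                 predicted = pred, f1_variant = f1),
            class = "pg_eval")
}

#' @export
print.pg_eval <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%  %s-F1 %.1f%%\n", x$accuracy, x$f1_variant,
              x$f1))
  print(x$confusion)
  invisible(x)
}
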