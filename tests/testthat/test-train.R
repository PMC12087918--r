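test_that("cross-entropy matches closed forms and direct summation", {
  onehot <- diag(3)[c(1, 2, 3), ]
  expect_equal(cross_entropy(onehot, 1:3), 0, tolerance = 1e-9)
  unif <- matrix(1 / 4, 5, 4)
  expect_equal(cross_entropy(unif, rep(2, 5)), log(4))
  set.seed(21)
  p <- matrix(runif(40), 10, 4)
  p <- p / rowSums(p)
  y <- sample(4, 10, replace = TRUE)
  naive <- -sum(vapply(1:10, function(i) log(p[i, y[i]]), numeric(1))) / 10
  expect_equal(cross_entropy(p, y), naive, tolerance = 1e-12)
  expect_error(cross_entropy(p * 2, y), "sum to 1")
  expect_error(cross_entropy(p, rep(9, 10)), "out of range")
})

test_that("distance loss: degenerate cases and singleton closed form", {
  set.seed(22)
  emb <- matrix(rnorm(40), 4, 10)
  # one domain per class: no pairs, loss 0
  expect_equal(distance_loss(emb, rep(1:2, 5), rep(1L, 10), 1), 0)
  # two domains with identical embedding sets: mmd(U, U) = 0
  e2 <- cbind(emb[, 1:5], emb[, 1:5])
  expect_equal(distance_loss(e2, rep(1L, 10), rep(1:2, each = 5), 1), 0,
               tolerance = 1e-12)
  # two singleton domains at distance sqrt(2) sigma: 2 (1 - e^-1)
  sigma <- 1.5
  e3 <- matrix(c(0, sqrt(2) * sigma), 1, 2)
  expect_equal(distance_loss(e3, c(1L, 1L), c(1L, 2L), sigma),
               2 * (1 - exp(-1)), tolerance = 1e-12)
  expect_gte(distance_loss(emb, rep(1:2, 5), rep(1:2, each = 5), 0.8), 0)
})

test_that("distance-loss gradient agrees with finite differences", {
  set.seed(23)
  emb <- matrix(rnorm(24), 3, 8)
  labels <- rep(1:2, each = 4)
  domains <- rep(c(1L, 2L), 4)
  sigma <- 1.1
  res <- physiogasf:::distance_loss_grad(emb, labels, domains, sigma)
  eps <- 1e-6
  for (i in sample(length(emb), 6)) {
    ep <- emb; ep[i] <- ep[i] + eps
    em <- emb; em[i] <- em[i] - eps
    num <- (distance_loss(ep, labels, domains, sigma) -
              distance_loss(em, labels, domains, sigma)) / (2 * eps)
    expect_equal(res$grad[i], num, tolerance = 1e-5)
  }
})

test_that("l2 penalty sums squared weights only", {
  fake <- list(cls = list(w = matrix(c(1, 2, 2, 1), 2, 2), b = c(9, 9)),
               bn = list(gamma = c(5, 5), beta = c(5, 5)))
  expect_equal(l2_penalty(fake), 10)
  model <- build_rbfe(rbfe_config(num_classes = 2, base_width = 2,
                                  embed_dim = 4), c(7, 4, 4), seed = 30)
  flat <- physiogasf:::flatten_params(model)
  brute <- sum(vapply(names(flat), function(k) {
    if (grepl("\\.w$", k)) sum(flat[[k]]^2) else 0
  }, numeric(1)))
  expect_equal(l2_penalty(model), brute, tolerance = 1e-12)
  expect_gt(l2_penalty(model), 0)          # Kaiming init is nonzero
  zeroed <- lapply(flat, function(x) x * 0)
  expect_equal(l2_penalty(physiogasf:::assign_params(model, zeroed)), 0)
})

test_that("stratified batches cover each epoch once and pair domains", {
  labels <- rep(1:2, each = 200)
  domains <- rep(rep(1:2, each = 100), 2)
  batches <- make_batches(labels, domains, 40, seed = 5)
  expect_identical(sort(unname(unlist(batches))), 1:400)
  for (b in batches) {
    cells <- table(labels[b], domains[b])
    expect_true(any(rowSums(cells > 0) >= 2))
  }
  expect_identical(batches, make_batches(labels, domains, 40, seed = 5))
  expect_false(identical(batches, make_batches(labels, domains, 40,
                                               seed = 6)))
})

test_that("chronological split follows the floor-then-remainder rule", {
  s <- chronological_split(1:100, c(8, 1, 1))
  expect_identical(lengths(s), c(train = 80L, validation = 10L, test = 10L))
  expect_identical(s$train, 1:80)
  expect_identical(s$test, 91:100)
  s2 <- chronological_split(1:101, c(8, 1, 1))
  expect_identical(lengths(s2), c(train = 81L, validation = 10L, test = 10L))
  # shuffled input is re-sorted by index
  s3 <- chronological_split(sample(1:100), c(8, 1, 1))
  expect_identical(s3$train, 1:80)
  expect_error(chronological_split(1:5, c(98, 1, 1)), "too few")
  # boundary windows sharing rows with the previous partition are flagged
  s4 <- chronological_split(1:100, c(8, 1, 1), window_size = 6)
  expect_identical(attr(s4, "boundary_overlap"),
                   c(validation = 5L, test = 5L))
})

test_that("classification report matches hand-computed confusion metrics", {
  y <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3)
  pred <- c(1, 1, 2, 2, 2, 3, 3, 3, 1, 3)
  rep <- physiogasf:::classification_report(pred, y, 3)
  expect_equal(rep$accuracy, 70)    # 7 of 10 on the diagonal
  expect_equal(unname(rowSums(rep$confusion)), c(3, 3, 4))
  # per-class F1 by hand: precision/recall per class
  f1_1 <- 2 * (2/3) * (2/3) / (2/3 + 2/3)
  f1_2 <- 2 * (2/3) * (2/3) / (2/3 + 2/3)
  f1_3 <- 2 * (3/4) * (3/4) / (3/4 + 3/4)
  expect_equal(rep$f1, 100 * mean(c(f1_1, f1_2, f1_3)))
  perfect <- physiogasf:::classification_report(y, y, 3)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f1, 100)
  expect_true(all(perfect$confusion[row(perfect$confusion) !=
                                      col(perfect$confusion)] == 0))
})

encoded_toy_task <- function(n_rows = 60, seed = 31) {
  # two classes with strongly different feature levels: trivially separable;
  # long class blocks keep boundary-straddling windows rare
  set.seed(seed)
  labels <- rep(rep(1:2, each = n_rows / 2), length.out = n_rows)
  vals <- matrix(rnorm(n_rows * 4, sd = 0.3), n_rows, 4) + 2 * (labels - 1)
  fm <- structure(list(values = vals, labels = labels, layout = NULL,
                       subseries_duration = 1),
                  class = "pg_features")
  encode_dataset(fm, 4)
}

test_that("loss history obeys the decomposition identity", {
  data <- encoded_toy_task()
  cfg <- pipeline_config(window_size = 4, batch_size = 16, n_epochs = 2,
                         lambda = 0.05, eta = 1e-4, seed = 3)
  part <- structure(data.frame(index = data$index, class = data$y,
                               domain = rep(1:2,
                                            length.out = length(data$y))),
                    class = c("pg_partition", "data.frame"))
  model <- build_rbfe(rbfe_config(num_classes = 2, base_width = 2,
                                  embed_dim = 4), c(4, 4, 4), seed = 32)
  fit <- train_rbfe(model, data, part, cfg)
  h <- fit$history
  expect_true(all(abs(h$l_total - (h$l_cls + h$lambda * h$l_dis +
                                     h$eta * h$l_reg)) < 1e-9))
  expect_true(all(h$l_cls >= 0 & h$l_dis >= 0 & h$l_reg >= 0))
  expect_gt(h$l_reg[1], 0)
  expect_gt(max(h$l_dis), 0)
})

test_that("lambda = eta = 0 reduces training to plain cross-entropy", {
  data <- encoded_toy_task()
  cfg <- pipeline_config(window_size = 4, batch_size = 16, n_epochs = 2,
                         lambda = 0, eta = 0, seed = 3)
  model <- build_rbfe(rbfe_config(num_classes = 2, base_width = 2,
                                  embed_dim = 4), c(4, 4, 4), seed = 32)
  fit <- train_rbfe(model, data, NULL, cfg)
  expect_identical(fit$history$l_total, fit$history$l_cls)
  expect_true(all(fit$history$l_dis == 0))
})

test_that("a small model learns a separable task and training is deterministic", {
  data <- encoded_toy_task(n_rows = 100)
  cfg <- pipeline_config(window_size = 4, batch_size = 32, n_epochs = 40,
                         lambda = 0, eta = 0, dropout_rate = 0, seed = 9)
  model <- build_rbfe(rbfe_config(num_classes = 2, base_width = 4,
                                  embed_dim = 8, dropout_rate = 0),
                      c(4, 4, 4), seed = 33)
  fit <- train_rbfe(model, data, NULL, cfg)
  rep <- evaluate_model(fit$model, data)
  expect_gte(rep$accuracy, 95)
  # bit-identical rerun under the same seeds
  model2 <- build_rbfe(rbfe_config(num_classes = 2, base_width = 4,
                                   embed_dim = 8, dropout_rate = 0),
                       c(4, 4, 4), seed = 33)
  fit2 <- train_rbfe(model2, data, NULL, cfg)
  expect_identical(fit$history$l_total, fit2$history$l_total)
  expect_identical(evaluate_model(fit2$model, data)$accuracy, rep$accuracy)
})
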