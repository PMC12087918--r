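# Independent brute-force oracles used to pin down expected values.

# Direct O(N^2) evaluation of the DFT sum.
naive_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1L), function(j) {
    sum(x * exp(-1i * 2 * pi * j * (0:(n - 1L)) / n))
  }, complex(1))
}

# Direct evaluation of the windowed periodogram over all N bins.
naive_windowed_psd <- function(x, z) {
  n <- length(x)
  bigz <- mean(z^2)
  vapply(0:(n - 1L), function(j) {
    Mod(sum(z * x * exp(-1i * 2 * pi * j * (0:(n - 1L)) / n)))^2 / (bigz * n)
  }, numeric(1))
}

# Two-pass mean / sample standard deviation by direct summation.
naive_time_features <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  c(m, sqrt(sum((x - m)^2) / (n - 1)))
}

# Three-term Gaussian-kernel MMD by explicit loops.
naive_mmd <- function(u, v, sigma) {
  ker <- function(a, b) exp(-sum((a - b)^2) / (2 * sigma^2))
  a <- nrow(u); b <- nrow(v)
  t1 <- 0; for (i in 1:a) for (j in 1:a) t1 <- t1 + ker(u[i, ], u[j, ])
  t2 <- 0; for (i in 1:b) for (j in 1:b) t2 <- t2 + ker(v[i, ], v[j, ])
  t3 <- 0; for (i in 1:a) for (j in 1:b) t3 <- t3 + ker(u[i, ], v[j, ])
  t1 / a^2 + t2 / b^2 - 2 * t3 / (a * b)
}

# Small synthetic recording used by several IO / featurization tests.
toy_recording <- function(duration = 10, rates = c(4, 8), seed = 42) {
  set.seed(seed)
  channels <- lapply(seq_along(rates), function(i) {
    list(spec = channel_spec(paste0("CH", i), rates[i], "a.u."),
         samples = rnorm(duration * rates[i]))
  })
  raw_recording(channels, labels = rep(1:2, length.out = duration),
                label_rate = 1, subject_id = "TOY", duration = duration)
}
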