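# Independent brute-force oracle for the periodized filter bank: scalar
# loops and explicit modular indexing, no code shared with the package
# internals. Valid for signal lengths divisible by 2^level.

oracle_dwt_step <- function(x, filt) {
  n <- length(x)
  taps <- length(filt)
  half <- n / 2
  out <- numeric(half)
  for (k in 0:(half - 1)) {
    acc <- 0
    for (m in 0:(taps - 1)) {
      j <- (2 * k + taps / 2 - m) %% n
      if (j < 0) j <- j + n
      acc <- acc + filt[m + 1] * x[j + 1]
    }
    out[k + 1] <- acc
  }
  out
}

oracle_dwt <- function(x, wavelet, level) {
  w <- get_wavelet(wavelet)
  details <- list()
  a <- x
  for (j in seq_len(level)) {
    d <- oracle_dwt_step(a, w$dec_hi)
    a <- oracle_dwt_step(a, w$dec_lo)
    details[[j]] <- d
  }
  list(approximation = a, details = details)
}

# Well-separated Gaussian blobs in feature space: an easy k-class problem
# for classifier-contract tests.
make_blobs <- function(n_per_class, k = 7, p = 10, sep = 6, sd = 1,
                       seed = 1) {
  set.seed(seed)
  centres <- matrix(stats::rnorm(k * p), k, p)
  centres <- centres / sqrt(rowSums(centres^2)) * sep
  x <- do.call(rbind, lapply(seq_len(k), function(c_i) {
    matrix(stats::rnorm(n_per_class * p, sd = sd), n_per_class, p,
           byrow = TRUE) + matrix(centres[c_i, ], n_per_class, p,
                                  byrow = TRUE)
  }))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = as.data.frame(x),
       y = factor(rep(paste0("A", seq_len(k)), each = n_per_class),
                  levels = paste0("A", seq_len(k))))
}

# One deterministic 9 s log + window for feature tests.
test_window <- function(rate = 25, length = 5, label = "A3", seed = 5) {
  log <- simulate_log(label, device_profile("htc_desire",
                                            sampling_rate = rate),
                      seed = seed)
  segment_window(log, length)
}
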