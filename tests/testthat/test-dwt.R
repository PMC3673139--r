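test_that("constant signals have zero detail and the expected approximation", {
  co1 <- dwt_decompose(c(1, 1, 1, 1), "haar", 1)
  expect_equal(co1$approximation, c(sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(co1$details[[1]], c(0, 0), tolerance = 1e-12)

  co2 <- dwt_decompose(c(1, 1, 1, 1), "haar", 2)
  expect_equal(co2$approximation, 2, tolerance = 1e-12)
  expect_equal(co2$details[[2]], 0, tolerance = 1e-12)
  expect_equal(co2$details[[1]], c(0, 0), tolerance = 1e-12)
})

test_that("coefficient lengths follow the dyadic N/2^j arithmetic", {
  set.seed(3)
  for (n in c(64, 96)) {  # 96 is padded to 128 at level 5
    x <- rnorm(n)
    for (lev in c(1, 3, 5)) {
      co <- dwt_decompose(x, "db2", lev)
      expect_equal(length(co$approximation), co$n / 2^lev)
      expect_equal(lengths(co$details), co$n / 2^seq_len(lev))
      # successive halving
      expect_equal(co$n %% 2^lev, 0)
    }
  }
})

test_that("perfect reconstruction holds across the whole registry", {
  set.seed(7)
  x <- rnorm(64)
  for (nm in wavelet_names()) {
    for (lev in c(1, 2, 4)) {
      co <- dwt_decompose(x, nm, lev)
      expect_lt(max(abs(idwt_reconstruct(co) - x)), 1e-8,
                label = sprintf("PR error for %s level %d", nm, lev))
    }
  }
})

test_that("reconstruction also inverts padded, non-dyadic windows", {
  set.seed(8)
  for (n in c(75, 144, 225)) {
    x <- rnorm(n)
    for (nm in c("haar", "db4", "bior3.3")) {
      co <- dwt_decompose(x, nm, 3)
      expect_equal(co$n_input, n)
      expect_lt(max(abs(idwt_reconstruct(co) - x)), 1e-8)
    }
  }
})

test_that("Parseval energy equality holds for orthogonal wavelets", {
  set.seed(9)
  x <- rnorm(128)
  for (nm in wavelet_names()) {
    w <- get_wavelet(nm)
    if (!w$orthogonal) next
    co <- dwt_decompose(x, w, 3)
    expect_equal(total_energy(co), sum(x^2), tolerance = 1e-10,
                 label = sprintf("Parseval for %s", nm))
  }
})

test_that("transform agrees with the brute-force convolution oracle", {
  set.seed(10)
  x64 <- rnorm(64)
  co <- dwt_decompose(x64, "db4", 2)
  or <- oracle_dwt(x64, "db4", 2)
  expect_equal(co$approximation, or$approximation, tolerance = 1e-12)
  expect_equal(co$details, or$details, tolerance = 1e-12)

  for (nm in c("haar", "db7", "sym5", "coif2", "bior2.4", "rbio3.5")) {
    for (n in c(16, 32, 64)) {
      x <- rnorm(n)
      co <- dwt_decompose(x, nm, 2)
      or <- oracle_dwt(x, nm, 2)
      expect_equal(co$approximation, or$approximation, tolerance = 1e-10,
                   label = sprintf("%s approximation, n=%d", nm, n))
      expect_equal(co$details, or$details, tolerance = 1e-10,
                   label = sprintf("%s details, n=%d", nm, n))
    }
  }
})

test_that("zero coefficients reconstruct to the zero vector", {
  co <- dwt_decompose(rnorm(32), "db3", 2)
  co$approximation[] <- 0
  co$details <- lapply(co$details, function(d) d * 0)
  expect_equal(idwt_reconstruct(co), rep(0, 32))
})

test_that("invalid arguments are rejected", {
  expect_error(dwt_decompose(rnorm(16), "db2", 0), "positive integer")
  expect_error(dwt_decompose(rnorm(16), "db2", 8), "at most 7")
  expect_error(dwt_decompose(numeric(0), "haar", 1), "at least 2")
  expect_error(dwt_decompose(c(1, NA, 3, 4), "haar", 1), "non-finite")
  expect_error(dwt_decompose(c(1, 2), "db10", 1), "too short")
  co <- dwt_decompose(rnorm(32), "db3", 2)
  co$details[[2]] <- co$details[[2]][-1]
  expect_error(idwt_reconstruct(co), "inconsistent length")
})
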