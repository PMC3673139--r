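test_that("total energy sums squared coefficients (and Parseval holds)", {
  co <- dwt_decompose(c(1, 1, 1, 1), "haar", 2)
  expect_equal(total_energy(co), 4, tolerance = 1e-12)  # A_2 = (2)

  co_alt <- dwt_decompose(c(1, -1, 1, -1), "haar", 1)
  expect_equal(co_alt$approximation, c(0, 0), tolerance = 1e-12)
  expect_equal(abs(co_alt$details[[1]]), c(sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  expect_equal(total_energy(co_alt), 4, tolerance = 1e-12)

  set.seed(13)
  x <- rnorm(64)
  expect_equal(total_energy(dwt_decompose(x, "db4", 3)), sum(x^2),
               tolerance = 1e-8)
})

test_that("energy ratios partition the energy and handle degenerate input", {
  co <- dwt_decompose(rep(2, 16), "db2", 2)
  er <- energy_ratios(co)
  expect_equal(er$EDR_A, 1, tolerance = 1e-9)
  expect_equal(er$EDR_D, c(0, 0), tolerance = 1e-9)

  co_alt <- dwt_decompose(c(1, -1, 1, -1), "haar", 1)
  er_alt <- energy_ratios(co_alt)
  expect_equal(er_alt$EDR_A, 0, tolerance = 1e-12)
  expect_equal(er_alt$EDR_D, 1, tolerance = 1e-12)

  set.seed(14)
  for (lev in 1:4) {
    er_r <- energy_ratios(dwt_decompose(rnorm(64), "sym4", lev))
    expect_equal(er_r$EDR_A + sum(er_r$EDR_D), 1, tolerance = 1e-9)
    expect_true(all(c(er_r$EDR_A, er_r$EDR_D) >= 0))
  }

  co_zero <- dwt_decompose(rep(0, 8), "haar", 1)
  expect_warning(er_zero <- energy_ratios(co_zero), "zero total energy")
  expect_equal(er_zero$EDR_A, 1)
  expect_equal(er_zero$EDR_D, 0)
})

test_that("normalized variances match hand-computed values", {
  # A = (0,2), D = (1,-1): population variances (1, 1) -> (0.5, 0.5)
  co <- dwt_decompose(c(1, 1, 1, 1), "haar", 1)
  co$approximation <- c(0, 2)
  co$details[[1]] <- c(1, -1)
  expect_equal(coefficient_variances(co), c(0.5, 0.5))

  # zero-variance fallback is uniform
  co$approximation <- c(2, 2)
  co$details[[1]] <- c(0, 0)
  expect_equal(coefficient_variances(co), c(0.5, 0.5))

  set.seed(15)
  v <- coefficient_variances(dwt_decompose(rnorm(64), "coif1", 3))
  expect_length(v, 4L)
  expect_equal(sum(v), 1, tolerance = 1e-12)
})

test_that("feature vectors have the 6(1+i) layout with block sums of one", {
  w <- test_window()
  for (lev in 1:7) {
    f <- extract_features(w, "db2", lev)
    expect_length(f, 6 * (1 + lev))
    expect_equal(names(f), feature_names(lev))
    for (ax in c("x", "y", "z")) {
      edr <- f[grep(paste0("^", ax, "_EDR_"), names(f))]
      nv <- f[grep(paste0("^", ax, "_NVAR_"), names(f))]
      expect_equal(sum(edr), 1, tolerance = 1e-9)
      expect_equal(sum(nv), 1, tolerance = 1e-9)
      expect_true(all(edr >= 0 & edr <= 1))
    }
  }
})

test_that("features are invariant to amplitude scaling", {
  w <- test_window()
  f1 <- extract_features(w, "db4", 3)
  for (scale in c(0.5, 3, 10)) {
    w2 <- w
    w2$x <- w$x * scale
    w2$y <- w$y * scale
    w2$z <- w$z * scale
    f2 <- extract_features(w2, "db4", 3)
    expect_equal(as.numeric(f2), as.numeric(f1), tolerance = 1e-9,
                 label = sprintf("scale %g", scale))
  }
})

test_that("permuting axes permutes feature blocks identically", {
  w <- test_window()
  f <- extract_features(w, "db4", 2)
  w_swapped <- w
  w_swapped$x <- w$y
  w_swapped$y <- w$x
  f_swapped <- extract_features(w_swapped, "db4", 2)
  pick <- function(v, ax) as.numeric(v[grep(paste0("^", ax, "_"), names(v))])
  expect_equal(pick(f_swapped, "x"), pick(f, "y"))
  expect_equal(pick(f_swapped, "y"), pick(f, "x"))
  expect_equal(pick(f_swapped, "z"), pick(f, "z"))
})

test_that("identical axes give identical per-axis blocks", {
  w <- test_window()
  w$y <- w$x
  w$z <- w$x
  f <- extract_features(w, "haar", 1)
  expect_equal(as.numeric(f[1:4]), as.numeric(f[5:8]))
  expect_equal(as.numeric(f[1:4]), as.numeric(f[9:12]))
})

test_that("feature tables carry ids, labels and metadata columns", {
  logs <- simulate_dataset(n_per_activity = 2, seed = 16)
  ft <- feature_table(logs, "db4", 2, 5)
  expect_equal(nrow(ft), 14L)
  expect_equal(levels(ft$label), activity_labels())
  expect_equal(ncol(feature_matrix(ft)), 18L)
  expect_true(all(ft$wavelet == "db4" & ft$level == 2L))
})
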