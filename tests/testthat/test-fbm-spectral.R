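test_that("symmetric_index implements the reflection and is an involution", {
  expect_identical(symmetric_index(c(0, 0), 8), c(0L, 0L))
  expect_identical(symmetric_index(c(1, 3), 8), c(7L, 5L))
  expect_identical(symmetric_index(c(4, 4), 8), c(4L, 4L))  # Nyquist fixed point
  set.seed(42)
  for (i in 1:20) {
    k <- sample(0:15, 3, replace = TRUE)
    expect_identical(symmetric_index(symmetric_index(k, 16), 16),
                     as.integer(k))
  }
  expect_error(symmetric_index(c(8, 0), 8), "coordinates")
  expect_error(symmetric_index(c(-1, 0), 8), "coordinates")
})

test_that("folded_frequency maps indices to signed frequencies", {
  expect_identical(folded_frequency(5, 8), -3L)
  expect_identical(folded_frequency(4, 8), 4L)  # Nyquist folds to +n/2
  expect_identical(folded_frequency(c(0, 3), 8), c(0L, 3L))
  set.seed(1)
  k <- sample(0:31, 50, replace = TRUE)
  f <- folded_frequency(k, 32)
  expect_true(all(abs(f) <= 16))
  expect_true(all((f %% 32) == k))
})

test_that("spectral amplitude follows the fBm power law", {
  expect_equal(spectral_amplitude(1, 0.3, 2, g = 1), 1)
  expect_equal(spectral_amplitude(4, 0.5, 2, g = 1), 0.125)  # 4^-1.5
  expect_error(spectral_amplitude(0, 0.5, 2, g = 1), "positive")
  # Monte Carlo check of the spectral-density condition: the mean squared
  # amplitude over many draws equals r^-(2H+D)
  set.seed(7)
  g <- rnorm(1e5)
  for (case in list(c(r = 2, H = 0.3, D = 2), c(r = 5, H = 0.8, D = 3))) {
    a <- spectral_amplitude(case["r"], case["H"], case["D"], g)
    ratio <- mean(a^2) / case[["r"]]^-(2 * case[["H"]] + case[["D"]])
    expect_equal(unname(ratio), 1, tolerance = 0.02)
  }
})

test_that("composite Hurst exponent is the |f|-weighted average", {
  expect_equal(composite_hurst(c(3, -2, 7), rep(0.4, 3)), 0.4)
  expect_equal(composite_hurst(c(1, 0), c(0.1, 0.9)), 0.1)
  expect_equal(composite_hurst(c(2, 2), c(0.1, 0.9)), 0.5)
  expect_equal(composite_hurst(c(-1, 3), c(0.2, 0.6)), (0.2 + 3 * 0.6) / 4)
  expect_error(composite_hurst(c(0, 0), c(0.1, 0.9)), "nonzero")
  # bounded by the extreme per-dimension exponents
  set.seed(3)
  for (i in 1:20) {
    f <- sample(-4:4, 3, replace = TRUE)
    if (all(f == 0)) f[1] <- 1
    h <- runif(3, 0.05, 0.95)
    ch <- composite_hurst(f, h)
    expect_gte(ch, min(h)); expect_lte(ch, max(h))
  }
})

test_that("algorithm 2 coefficients are exactly conjugate-symmetric", {
  for (seed in c(1, 2, 3)) {
    f <- fbm_spectral_field(16, dims = 2, hurst = 0.4, seed = seed,
                            algorithm = 2)
    expect_identical(max_symmetry_violation(f$coefficients), 0)
    # self-symmetric coordinates carry exactly zero imaginary part
    A <- f$coefficients
    for (ky in c(0, 8)) for (kx in c(0, 8))
      expect_identical(Im(A[ky + 1, kx + 1]), 0)
    expect_identical(A[1, 1], 0 + 0i)  # DC coefficient fully zeroed
  }
  # also in 3-D
  f3 <- fbm_spectral_field(8, dims = 3, hurst = 0.6, seed = 5, algorithm = 2)
  expect_identical(max_symmetry_violation(f3$coefficients), 0)
})

test_that("algorithm 2 output is real, mean-zero and deterministic", {
  land <- fbm_landscape(32, dims = 2, hurst = 0.5, seed = 11, algorithm = 2)
  expect_lte(land$imag_rms_ratio, 1e-9)
  expect_lte(abs(mean(land)), 1e-10 * sd(as.vector(land$values)))
  expect_true(all(is.finite(land$values)))
  expect_true(land$periodic)
  land2 <- fbm_landscape(32, dims = 2, hurst = 0.5, seed = 11, algorithm = 2)
  expect_identical(land$values, land2$values)
})

test_that("algorithm 1 violates conjugate symmetry and discards information", {
  f <- fbm_spectral_field(16, dims = 2, hurst = 0.5, seed = 11, algorithm = 1)
  expect_gt(max_symmetry_violation(f$coefficients), 0.01)
  land <- inverse_transform(f)
  expect_gt(land$imag_rms_ratio, 1e-6)
  # deterministic too
  land2 <- fbm_landscape(16, dims = 2, hurst = 0.5, seed = 11, algorithm = 1)
  expect_identical(land$values, land2$values)
})

test_that("a single conjugate pair inverts to a pure cosine", {
  A <- array(0 + 0i, dim = 8)
  A[2] <- 1 + 0i  # k = 1
  A[8] <- 1 + 0i  # k* = 7
  land <- inverse_transform(A)
  expect_lte(land$imag_rms_ratio, 1e-12)
  expect_equal(as.vector(land$values), 2 / 8 * cos(2 * pi * (0:7) / 8),
               tolerance = 1e-12)
})

test_that("inverse_transform is linear", {
  z <- array(0 + 0i, dim = c(4, 4))
  expect_identical(as.vector(inverse_transform(z)$values), rep(0, 16))
  set.seed(2)
  f <- fbm_spectral_field(8, 2, 0.5, seed = 2, algorithm = 2)
  a <- inverse_transform(f$coefficients)
  b <- inverse_transform(3 * f$coefficients)
  expect_equal(b$values, 3 * a$values, tolerance = 1e-12)
})

test_that("invalid parameters are rejected", {
  expect_error(fbm_landscape(31, hurst = 0.5), "power of two")
  expect_error(fbm_landscape(32, hurst = 1.5), "strictly in \\(0, 1\\)")
  expect_error(fbm_landscape(32, hurst = 0), "strictly in \\(0, 1\\)")
  expect_error(fbm_landscape(32, dims = 0, hurst = 0.5), "dims")
  expect_error(fbm_landscape(32, dims = 2, hurst = c(0.2, 0.4, 0.6)),
               "per dimension")
})

test_that("spectral-slope regression recovers the generating Hurst exponent", {
  for (H in c(0.1, 0.5, 0.9)) {
    est <- mean(vapply(1:20, function(s) {
      suppressWarnings(as.numeric(
        estimate_hurst(fbm_landscape(128, 2, H, seed = s))))
    }, numeric(1)))
    expect_lte(abs(est - H), 0.1)
  }
})

test_that("white noise is flagged as out of the fBm model", {
  set.seed(4)
  land <- new_landscape(array(rnorm(64 * 64), c(64, 64)), periodic = TRUE)
  expect_warning(h <- estimate_hurst(land), "outside \\(0, 1\\)")
  expect_false(attr(h, "in_model"))
  expect_lt(as.numeric(h), 0.05)  # flat spectrum implies H near -D/2
  expect_error(estimate_hurst(new_landscape(array(1, c(8, 8)))), "constant")
})

test_that("autocorrelation at distance 1 increases with the Hurst exponent", {
  net <- build_network(32, 90)
  mean_i <- vapply(c(0.1, 0.5, 0.9), function(H) {
    mean(vapply(1:50, function(s)
      morans_i(fbm_landscape(32, 2, H, seed = 1000 + s), net, 1),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_i) > 0))
})

test_that("dimension-specific Hurst exponents control per-axis smoothness", {
  # rough along dim 1 / rows (H = 0.1), smooth along dim 2 / columns
  # (H = 0.9): the horizontal correlogram should sit above the vertical one
  i_v <- i_h <- numeric(10)
  for (s in 1:10) {
    land <- fbm_landscape(32, dims = 2, hurst = c(0.1, 0.9), seed = 300 + s)
    i_v[s] <- morans_i(land, build_network(32, 0), 1)   # along dim 1 (rows)
    i_h[s] <- morans_i(land, build_network(32, 90), 1)  # along dim 2 (cols)
  }
  expect_gt(mean(i_h) - mean(i_v), 0)
})
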