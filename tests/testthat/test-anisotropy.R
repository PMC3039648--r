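test_that("directional networks partition the torus into n cycles of n cells", {
  for (th in c(0, 45, 90, 135)) {
    net <- build_network(4, th)
    expect_identical(dim(net$cycles), c(4L, 4L))
    expect_identical(sort(as.vector(net$cycles)), 1:16)  # disjoint cover
    # consecutive cells along a cycle are one step apart in the direction
    step <- switch(as.character(th), "0" = c(0, 1), "45" = c(1, 1),
                   "90" = c(1, 0), "135" = c(1, -1))
    for (s in 1:4) for (t in 1:4) {
      id <- net$cycles[s, t]
      nxt <- net$cycles[s, t %% 4 + 1]
      y <- (id - 1) %% 4; x <- (id - 1) %/% 4
      yn <- (nxt - 1) %% 4; xn <- (nxt - 1) %/% 4
      expect_identical(c((x + step[1]) %% 4, (y + step[2]) %% 4),
                       c(xn, yn))
    }
  }
  expect_error(build_network(4, 30), "theta")
})

test_that("horizontal cycles are the rows", {
  net <- build_network(4, 90)
  rows <- apply(net$cycles, 1, function(ids) unique((ids - 1) %% 4))
  expect_identical(sort(as.integer(rows)), 0:3)
  expect_identical(length(as.vector(net$cycles)), 16L)  # 16 distance-1 links
})

test_that("checkerboard Moran's I is exactly -1 then +1 on the horizontal network", {
  cb <- checkerboard(4)
  net <- build_network(4, 90)
  expect_identical(morans_i(cb, net, 1), -1)
  expect_identical(morans_i(cb, net, 2), 1)
})

test_that("morans_i matches the brute-force double-sum oracle", {
  set.seed(17)
  nets <- lapply(c(0, 45, 90, 135), function(th) build_network(6, th))
  for (rep in 1:50) {
    v <- matrix(rnorm(36), 6)
    net <- nets[[(rep - 1) %% 4 + 1]]
    for (d in 1:3)
      expect_equal(morans_i(v, net, d), brute_morans_i(v, net, d),
                   tolerance = 1e-12)
  }
})

test_that("morans_i validates its inputs", {
  net <- build_network(4, 0)
  expect_error(morans_i(matrix(1, 4, 4), net, 1), "constant")
  expect_error(morans_i(matrix(rnorm(16), 4), net, 3), "1..n/2")
  expect_error(morans_i(matrix(rnorm(36), 6), net, 1), "side length")
})

test_that("permutation mean of Moran's I is -1/(N-1)", {
  set.seed(5)
  v <- matrix(rnorm(16), 4)
  net <- build_network(4, 45)
  perm_i <- vapply(1:4000, function(i)
    morans_i(matrix(sample(as.vector(v)), 4), net, 1), numeric(1))
  expect_lt(abs(mean(perm_i) - (-1 / 15)), 0.01)
})

test_that("rotating the landscape swaps perpendicular directions exactly", {
  set.seed(8)
  v <- matrix(rnorm(64), 8)
  rot <- t(v)[, 8:1]  # 90 degree rotation
  for (d in 1:4) {
    expect_equal(morans_i(v, build_network(8, 0), d),
                 morans_i(rot, build_network(8, 90), d), tolerance = 1e-12)
    expect_equal(morans_i(v, build_network(8, 45), d),
                 morans_i(rot, build_network(8, 135), d), tolerance = 1e-12)
  }
})

test_that("toroidal translation leaves every Moran's I unchanged", {
  set.seed(12)
  v <- matrix(rnorm(64), 8)
  shifted <- v[c(4:8, 1:3), c(7:8, 1:6)]
  for (th in c(0, 45, 90, 135)) for (d in c(1, 3)) {
    expect_equal(morans_i(v, build_network(8, th), d),
                 morans_i(shifted, build_network(8, th), d),
                 tolerance = 1e-12)
  }
})

test_that("permutation significance flags strong autocorrelation", {
  land <- fbm_landscape(16, hurst = 0.9, seed = 21)
  net <- build_network(16, 90)
  res <- permutation_significance(land, net, 1, permutations = 199, seed = 1)
  expect_identical(res$flag, "high")
  expect_lt(res$p_value, 0.05)
})

test_that("the empirical p-value follows the (r+1)/(M+1) rule", {
  # observed I above every permuted value -> p = 1/(M+1)
  land <- fbm_landscape(16, hurst = 0.9, seed = 2)
  net <- build_network(16, 0)
  res <- permutation_significance(land, net, 1, permutations = 99, seed = 3)
  expect_identical(res$p_value, 1 / 100)
  expect_error(permutation_significance(land, net, 1, permutations = 50),
               "at least 99")
})

test_that("type-I error of the permutation flag is near alpha on noise", {
  set.seed(31)
  net <- build_network(8, 90)
  flags <- vapply(1:200, function(i) {
    v <- matrix(rnorm(64), 8)
    permutation_significance(v, net, 1, permutations = 99,
                             alpha = 0.1)$flag
  }, "")
  rate <- mean(flags != "ns")
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.25)
})

test_that("correlogram tables cover every direction and distance", {
  land <- fbm_landscape(16, hurst = 0.6, seed = 10)
  tab <- correlogram(land, permutations = 0)
  expect_identical(nrow(tab), 4L * 8L)
  expect_true(all(is.finite(tab$morans_i)))
  tab99 <- correlogram(land, permutations = 99, seed = 1)
  expect_true(all(tab99$p_value >= 1 / 100 & tab99$p_value <= 1))
  expect_true(all(tab99$flag %in% c("high", "low", "ns")))
  # at H = 0.6 the nearest distance class is significantly autocorrelated
  expect_true(all(tab99$flag[tab99$distance == 1] == "high"))
})

test_that("delta statistics subtract perpendicular directions", {
  tab <- tibble::tibble(
    direction = rep(c(0, 45, 90, 135), each = 2),
    distance = rep(1:2, 4),
    morans_i = c(0.5, 0.4, 0.3, 0.2, 0.3, 0.1, 0.25, 0.15))
  ds <- delta_statistics(tab)
  expect_equal(ds$delta_cardinal, c(0.2, 0.3))
  expect_equal(ds$delta_diagonal, c(0.05, 0.05))
  expect_error(delta_statistics(tab[tab$direction != 45, ]), "four")
})

test_that("transposing the landscape negates the cardinal delta", {
  set.seed(14)
  v <- matrix(rnorm(64), 8)
  d1 <- delta_statistics(correlogram(v, permutations = 0))
  d2 <- delta_statistics(correlogram(t(v), permutations = 0))
  expect_equal(d1$delta_cardinal, -d2$delta_cardinal, tolerance = 1e-12)
})

test_that("deltas on isotropic noise are centred on zero", {
  set.seed(77)
  d1 <- t(vapply(1:100, function(i) {
    v <- matrix(rnorm(64), 8)
    ds <- delta_statistics(correlogram(v, permutations = 0))
    c(ds$delta_cardinal[1], ds$delta_diagonal[1])
  }, numeric(2)))
  expect_gt(sign_test_p(d1[, 1]), 0.05)
  expect_gt(sign_test_p(d1[, 2]), 0.05)
})
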