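# Independent oracles used across the suite.

# Naive O(N^2) evaluation of Moran's I from its double-sum definition:
# I = N * sum_ij w_ij z_i z_j / (S0 * sum_i z_i^2), with w_ij = 1 iff cells
# i and j sit on the same cycle of the network at minimal wrap distance d.
brute_morans_i <- function(v, net, d) {
  n <- net$n
  n_cells <- n * n
  z <- as.vector(v) - mean(v)
  pos <- matrix(NA_integer_, n_cells, 2)
  for (s in seq_len(n)) for (t in seq_len(n))
    pos[net$cycles[s, t], ] <- c(s, t)
  w <- matrix(0, n_cells, n_cells)
  for (i in seq_len(n_cells)) for (j in seq_len(n_cells)) {
    if (i != j && pos[i, 1] == pos[j, 1]) {
      dt <- abs(pos[i, 2] - pos[j, 2])
      if (min(dt, n - dt) == d) w[i, j] <- 1
    }
  }
  n_cells * sum(w * outer(z, z)) / (sum(w) * sum(z^2))
}

# 0-based coordinates of every cell (column-major), mirroring the lattice
# layout used by the generators.
cell_coordinates <- function(extent) {
  idx <- 0:(prod(extent) - 1)
  co <- matrix(0L, length(idx), length(extent))
  stride <- 1
  for (d in seq_along(extent)) {
    co[, d] <- (idx %/% stride) %% extent[d]
    stride <- stride * extent[d]
  }
  co
}

# Conjugate-symmetry audit of a coefficient array: largest absolute
# difference between coeff(k) and Conj(coeff(k*)) over every index k.
max_symmetry_violation <- function(coefs) {
  n <- dim(coefs)[1]
  co <- cell_coordinates(dim(coefs))
  star <- (n - co) %% n
  lin <- as.vector(star %*% cumprod(c(1, dim(coefs)[-length(dim(coefs))]))) + 1
  max(Mod(as.vector(coefs) - Conj(as.vector(coefs)[lin])))
}

# +1/-1 checkerboard on an n x n lattice
checkerboard <- function(n) outer(0:(n - 1), 0:(n - 1),
                                  function(y, x) ifelse((x + y) %% 2 == 0, 1, -1))

sign_test_p <- function(x) {
  x <- x[x != 0]
  stats::binom.test(sum(x > 0), length(x))$p.value
}
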