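#' Piecewise-linear gradient surface
#'
#' A 2-D landscape whose value depends only on the coordinate along one
#' axis: `1 - |y - (n-1)/2| / (n/2)`, where `y` is the 0-based cell-centre
#' coordinate along the gradient axis and `n` the extent there.  Values are
#' bounded in (0, 1], symmetric about and maximal at the centre, decreasing
#' linearly towards the edges, and constant along the other axis.  Combined
#' with a normalised fractal landscape (see [combine()]) this models a
#' macro-scale environmental gradient overlaid with local spatially
#' correlated variability.
#'
#' @param extent two side lengths `(n_y, n_x)`, i.e. rows then columns.
#' @param axis which axis carries the gradient: 1 (rows/y, default) or 2
#'   (columns/x).
#' @return an aperiodic `fbm_landscape`.
#' @examples
#' g <- gradient_surface(c(256, 256))
#' range(as.matrix(g))  # within (0, 1]
#' @export
gradient_surface <- function(extent, axis = 1) {
  extent <- check_extent(extent)
  if (length(extent) != 2L) stop("`extent` must give two side lengths")
  if (!axis %in% c(1, 2)) stop("`axis` must be 1 or 2")
  n <- extent[axis]
  if (n < 2) stop("the gradient axis must have extent >= 2")
  profile <- 1 - abs(0:(n - 1) - (n - 1) / 2) / (n / 2)
  v <- if (axis == 1) matrix(profile, nrow = extent[1], ncol = extent[2])
       else matrix(profile, nrow = extent[1], ncol = extent[2], byrow = TRUE)
  new_landscape(v, periodic = FALSE)
}

#' Rescale a landscape to the unit interval
#'
#' Affine transform so the minimum maps to 0 and the maximum to 1.
#'
#' @param land an `fbm_landscape` (non-constant).
#' @return an `fbm_landscape` with the same metadata, values in \[0, 1\].
#' @export
normalize01 <- function(land) {
  stopifnot(is_landscape(land))
  v <- land$values
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("cannot normalise a constant landscape")
  out <- land
  out$values <- (v - rng[1]) / (rng[2] - rng[1])
  out
}

#' Linear combination of two landscapes
#'
#' Cellwise `w * a + (1 - w) * b`.  When both inputs lie in \[0, 1\] so does
#' the combination, which is the standard way to merge a gradient surface
#' with a normalised fractal landscape.
#'
#' @param a,b landscapes with identical extents.
#' @param w weight on `a`, in \[0, 1\].
#' @return an `fbm_landscape`; periodic only if both inputs are.
#' @export
combine <- function(a, b, w = 0.5) {
  stopifnot(is_landscape(a), is_landscape(b))
  if (!identical(a$extent, b$extent))
    stop("`a` and `b` must have identical extents")
  if (length(w) != 1L || is.na(w) || w < 0 || w > 1)
    stop("`w` must be a single weight in [0, 1]")
  new_landscape(w * a$values + (1 - w) * b$values,
                periodic = a$periodic && b$periodic)
}

#' Crop a landscape to a smaller extent
#'
#' Keeps the first cells in each dimension (pure windowing: retained values
#' are unchanged).  This is how arbitrary, non-power-of-two extents and
#' aperiodic landscapes are obtained from spectral synthesis output: generate
#' at the next power of two (or 2-4x larger when periodicity must be
#' thoroughly diluted) and crop.  Cropping any dimension clears the periodic
#' flag -- a cut torus no longer tiles.
#'
#' @param land an `fbm_landscape`.
#' @param extent desired extent, elementwise <= the source extent.
#' @return an `fbm_landscape`.
#' @export
crop <- function(land, extent) {
  stopifnot(is_landscape(land))
  extent <- check_extent(extent)
  if (length(extent) != length(land$extent))
    stop("`extent` must have one entry per dimension of `land`")
  if (any(extent > land$extent))
    stop("desired extent exceeds the source extent")
  if (all(extent == land$extent)) return(land)
  idx <- lapply(extent, seq_len)
  out <- land
  out$values <- do.call(`[`, c(list(land$values), idx, list(drop = FALSE)))
  out$extent <- extent
  out$periodic <- FALSE
  out
}

#' Generate an fBm landscape for an arbitrary extent
#'
#' Convenience wrapper: synthesises at the smallest power-of-two side length
#' covering the largest requested extent, then [crop()]s.
#'
#' @param extent desired extent per dimension.
#' @inheritParams fbm_landscape
#' @return an aperiodic `fbm_landscape` (unless `extent` is already a cubic
#'   power of two).
#' @examples
#' land <- fbm_for_extent(c(100, 60), hurst = 0.5, seed = 1)  # source n = 128
#' dim(land)
#' @export
fbm_for_extent <- function(extent, hurst = 0.5, seed = NULL, algorithm = 2) {
  extent <- check_extent(extent)
  n <- next_power_of_two(max(extent))
  land <- fbm_landscape(n, dims = length(extent), hurst = hurst, seed = seed,
                        algorithm = algorithm)
  crop(land, extent)
}

#' Extract a lower-dimensional section of a landscape
#'
#' Fixes one axis at a given position and returns the section, e.g. one time
#' slice of a 3-D spatio-temporal landscape generated with dimension-specific
#' Hurst exponents (smooth in space, rough or smooth in time).
#'
#' @param land an `fbm_landscape` with at least 2 dimensions.
#' @param axis axis to fix (1-based).
#' @param index 1-based position along that axis.
#' @return an `fbm_landscape` of one dimension fewer.
#' @examples
#' \donttest{
#' st <- fbm_landscape(32, dims = 3, hurst = c(0.9, 0.9, 0.1), seed = 1)
#' frame1 <- slice_axis(st, axis = 3, index = 1)
#' }
#' @export
slice_axis <- function(land, axis, index) {
  stopifnot(is_landscape(land))
  dims <- length(land$extent)
  if (dims < 2L) stop("`land` must have at least 2 dimensions")
  if (!axis %in% seq_len(dims)) stop("`axis` must be in 1..", dims)
  if (index != round(index) || index < 1 || index > land$extent[axis])
    stop("`index` out of range: must be in 1..", land$extent[axis])
  idx <- lapply(land$extent, seq_len)
  idx[[axis]] <- index
  v <- do.call(`[`, c(list(land$values), idx, list(drop = FALSE)))
  dim(v) <- land$extent[-axis]
  new_landscape(v, periodic = land$periodic, hurst = land$hurst[-axis],
                seed = land$seed, algorithm = land$algorithm)
}
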