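#' @importFrom stats fft rnorm runif median quantile lm coef sd
#' @importFrom rlang .data
NULL

#' Construct a continuous landscape object
#'
#' A landscape is an N-dimensional real-valued lattice together with a small
#' amount of metadata: whether the lattice tiles seamlessly (spectral
#' synthesis output is periodic until cropped), the Hurst exponent(s) used to
#' generate it, and the RNG seed, so any landscape can be regenerated from its
#' own record.
#'
#' @param values numeric array (a `dim` attribute is added for vectors).
#' @param periodic logical; does the lattice wrap seamlessly at its edges?
#' @param hurst optional numeric vector of Hurst exponents used (one per
#'   dimension).
#' @param seed optional integer seed used for generation.
#' @param algorithm optional integer, 1 (unconstrained benchmark) or 2
#'   (conjugate-symmetric).
#' @param imag_rms_ratio optional diagnostic: RMS of the imaginary component
#'   discarded after the inverse Fourier transform, relative to the RMS of the
#'   real part.
#' @return an object of class `fbm_landscape`.
#' @export
new_landscape <- function(values, periodic = FALSE, hurst = NULL, seed = NULL,
                          algorithm = NULL, imag_rms_ratio = NULL) {
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (is.null(dim(values))) dim(values) <- length(values)
  if (!all(is.finite(values))) stop("landscape values must all be finite")
  structure(
    list(values = values, extent = dim(values), periodic = isTRUE(periodic),
         hurst = hurst, seed = seed, algorithm = algorithm,
         imag_rms_ratio = imag_rms_ratio),
    class = "fbm_landscape")
}

#' @export
print.fbm_landscape <- function(x, ...) {
  cat("<fbm_landscape> ", paste(x$extent, collapse = " x "),
      if (x$periodic) " (periodic)" else " (aperiodic)", "\n", sep = "")
  if (!is.null(x$hurst))
    cat("  hurst: ", paste(format(x$hurst), collapse = ", "), "\n", sep = "")
  if (!is.null(x$algorithm))
    cat("  algorithm: ", x$algorithm, "\n", sep = "")
  if (!is.null(x$seed)) cat("  seed: ", x$seed, "\n", sep = "")
  cat("  values: [", format(min(x$values), digits = 4), ", ",
      format(max(x$values), digits = 4), "], mean ",
      format(mean(x$values), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
as.array.fbm_landscape <- function(x, ...) x$values

#' @export
as.matrix.fbm_landscape <- function(x, ...) {
  if (length(x$extent) != 2L)
    stop("only 2-D landscapes can be converted to a matrix")
  x$values
}

#' @export
dim.fbm_landscape <- function(x) x$extent

#' @export
mean.fbm_landscape <- function(x, ...) mean(x$values, ...)

is_landscape <- function(x) inherits(x, "fbm_landscape")

#' Construct a binary (suitable/unsuitable) landscape
#'
#' @param suitable logical array marking suitable cells.
#' @param seed optional integer seed used for generation.
#' @param model optional character tag naming the generating model.
#' @return an object of class `fbm_binary_landscape` with fields `suitable`,
#'   `extent`, `h` (the realised proportion of suitable cells) and metadata.
#' @export
new_binary_landscape <- function(suitable, seed = NULL, model = NULL) {
  if (!is.logical(suitable)) stop("`suitable` must be logical")
  if (is.null(dim(suitable))) dim(suitable) <- length(suitable)
  if (anyNA(suitable)) stop("`suitable` must not contain NA")
  structure(
    list(suitable = suitable, extent = dim(suitable),
         h = mean(suitable), seed = seed, model = model),
    class = "fbm_binary_landscape")
}

#' @export
print.fbm_binary_landscape <- function(x, ...) {
  cat("<fbm_binary_landscape> ", paste(x$extent, collapse = " x "),
      if (!is.null(x$model)) paste0(" [", x$model, "]") else "", "\n", sep = "")
  cat("  suitable: ", sum(x$suitable), " cells (h = ",
      format(x$h, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.fbm_binary_landscape <- function(x) x$extent

#' @export
as.array.fbm_binary_landscape <- function(x, ...) x$suitable

#' Number of suitable cells in a binary landscape
#' @param x an `fbm_binary_landscape`.
#' @return integer count of suitable cells.
#' @export
n_suitable <- function(x) {
  stopifnot(inherits(x, "fbm_binary_landscape"))
  sum(x$suitable)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a landscape into a tibble of cell records
#'
#' One row per cell, with 0-based integer coordinates `x1`, `x2`, ... (for 2-D
#' landscapes `x1` is the row/y coordinate and `x2` the column/x coordinate)
#' and the cell `value`.
#'
#' @param x an `fbm_landscape`.
#' @param ... unused.
#' @return a tibble with one row per cell.
#' @export
tidy.fbm_landscape <- function(x, ...) {
  ext <- x$extent
  co <- lattice_coordinates(ext)
  colnames(co) <- paste0("x", seq_along(ext))
  out <- tibble::as_tibble(as.data.frame(co))
  out$value <- as.vector(x$values)
  out
}

#' @rdname tidy.fbm_landscape
#' @export
tidy.fbm_binary_landscape <- function(x, ...) {
  ext <- x$extent
  co <- lattice_coordinates(ext)
  colnames(co) <- paste0("x", seq_along(ext))
  out <- tibble::as_tibble(as.data.frame(co))
  out$suitable <- as.vector(x$suitable)
  out
}

# 0-based coordinates of every cell of a lattice, column-major, one row per
# cell and one column per dimension.
lattice_coordinates <- function(extent) {
  n_cells <- prod(extent)
  idx <- 0:(n_cells - 1)
  co <- matrix(0L, nrow = n_cells, ncol = length(extent))
  stride <- 1
  for (d in seq_along(extent)) {
    co[, d] <- (idx %/% stride) %% extent[d]
    stride <- stride * extent[d]
  }
  co
}

#' Plot a two-dimensional landscape as a raster
#'
#' @param object an `fbm_landscape` or `fbm_binary_landscape` (2-D).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fbm_landscape <- function(object, ...) {
  if (length(object$extent) != 2L)
    stop("autoplot is only available for 2-D landscapes")
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x2, y = .data$x1,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "value") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fbm_landscape
#' @export
autoplot.fbm_binary_landscape <- function(object, ...) {
  if (length(object$extent) != 2L)
    stop("autoplot is only available for 2-D landscapes")
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x2, y = .data$x1,
                                   fill = .data$suitable)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white", `TRUE` = "black"),
                               name = "suitable") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
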