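#' Random percolation map
#'
#' The simplest binary neutral landscape: exactly `round(h * N)` of the `N`
#' cells are classified suitable, chosen uniformly at random without
#' replacement, equivalent to switching random unsuitable cells to suitable
#' one at a time until the requested proportion is reached.  The realised
#' count is exact, not binomial.
#'
#' @param extent integer vector of side lengths, one per dimension.
#' @param h requested proportion of suitable habitat, in \[0, 1\].
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return an `fbm_binary_landscape`.
#' @examples
#' perc <- random_percolation(c(16, 16), h = 0.25, seed = 1)
#' n_suitable(perc)  # exactly 64
#' @export
random_percolation <- function(extent, h, seed = NULL) {
  extent <- check_extent(extent)
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h < 0 || h > 1)
    stop("`h` must be a single proportion in [0, 1]")
  n_cells <- prod(extent)
  k <- round(h * n_cells)
  if (!is.null(seed)) set.seed(seed)
  suit <- logical(n_cells)
  if (k > 0) suit[sample.int(n_cells, k)] <- TRUE
  dim(suit) <- extent
  new_binary_landscape(suit, seed = seed, model = "percolation")
}

#' Define a hierarchical curdling plan
#'
#' Curdling assigns habitat at successively finer spatial resolutions: at
#' each stage the currently selected tiles are subdivided into smaller tiles
#' and a proportion `p_i` of the children within every selected parent are
#' retained.  The overall habitat proportion is the product of the stage
#' proportions.
#'
#' @param tile_sides integer vector of tile side lengths, strictly
#'   decreasing, each dividing the previous (and the landscape extent), with
#'   the final stage at single-cell resolution (side 1).
#' @param proportions selection proportion per stage, each in \[0, 1\].
#' @return a `curdling_plan` object.
#' @examples
#' # the three-stage plan for a 512 x 512 landscape: 75% of the 64x64 tiles,
#' # then 75% of the 8x8 tiles within those, then 50% of their cells
#' curdling_plan(c(64, 8, 1), c(0.75, 0.75, 0.5))
#' @export
curdling_plan <- function(tile_sides, proportions) {
  if (length(tile_sides) != length(proportions) || length(tile_sides) < 1L)
    stop("`tile_sides` and `proportions` must be non-empty and equal length")
  if (any(tile_sides != round(tile_sides)) || any(tile_sides < 1))
    stop("`tile_sides` must be positive integers")
  if (any(diff(tile_sides) >= 0))
    stop("`tile_sides` must be strictly decreasing")
  if (length(tile_sides) > 1L &&
      any(tile_sides[-length(tile_sides)] %% tile_sides[-1] != 0))
    stop("each tile side must divide the previous stage's tile side")
  if (tile_sides[length(tile_sides)] != 1L)
    stop("the final stage must be at single-cell resolution (tile side 1)")
  if (any(proportions < 0 | proportions > 1))
    stop("each stage proportion must lie in [0, 1]")
  structure(list(tile_sides = as.integer(tile_sides),
                 proportions = as.numeric(proportions)),
            class = "curdling_plan")
}

#' @export
print.curdling_plan <- function(x, ...) {
  cat("<curdling_plan> ", length(x$tile_sides), " stages\n", sep = "")
  for (i in seq_along(x$tile_sides))
    cat("  stage ", i, ": tiles of side ", x$tile_sides[i], ", p = ",
        x$proportions[i], "\n", sep = "")
  invisible(x)
}

#' Hierarchical curdling
#'
#' Generates a binary landscape by hierarchical curdling under a
#' [curdling_plan()].  At every stage, each selected parent tile is divided
#' into child tiles of the stage's side length and exactly
#' `round(p_i * n_children)` children are selected uniformly at random
#' (round-half-to-even).  Because per-parent selection uses exact counts, the
#' final number of suitable cells is the deterministic product of the stage
#' counts -- e.g. the classic 512 x 512 plan with proportions 0.75, 0.75, 0.5
#' over 64-cell, 8-cell and single-cell tiles always yields 73728 suitable
#' cells (about 28%), whatever the seed.
#'
#' @param extent integer vector of side lengths; every side must be divisible
#'   by the first stage's tile side.
#' @param plan a [curdling_plan()].
#' @inheritParams random_percolation
#' @return an `fbm_binary_landscape`.
#' @examples
#' plan <- curdling_plan(c(8, 1), c(0.75, 0.5))
#' curdle(c(64, 64), plan, seed = 1)
#' @export
curdle <- function(extent, plan, seed = NULL) {
  extent <- check_extent(extent)
  if (!inherits(plan, "curdling_plan")) stop("`plan` must be a curdling_plan")
  dims <- length(extent)
  if (any(extent %% plan$tile_sides[1] != 0))
    stop("every side of `extent` must be divisible by the first tile side (",
         plan$tile_sides[1], ")")
  if (!is.null(seed)) set.seed(seed)

  # selected tiles are tracked as a matrix of 0-based tile origins (cells)
  origins <- matrix(0L, nrow = 1, ncol = dims)
  parent_side <- NA_integer_
  for (stage in seq_along(plan$tile_sides)) {
    side <- plan$tile_sides[stage]
    p <- plan$proportions[stage]
    if (stage == 1L) {
      per_dim <- extent %/% side
    } else {
      per_dim <- rep(parent_side %/% side, dims)
    }
    n_children <- prod(per_dim)
    k <- round(p * n_children)
    child_offsets <- lattice_coordinates(per_dim) * side
    new_origins <- vector("list", nrow(origins))
    for (i in seq_len(nrow(origins))) {
      pick <- if (k > 0) sample.int(n_children, k) else integer(0)
      if (length(pick))
        new_origins[[i]] <- child_offsets[pick, , drop = FALSE] +
          rep(origins[i, ], each = length(pick))
    }
    origins <- do.call(rbind, new_origins)
    if (is.null(origins) || nrow(origins) == 0) {
      origins <- matrix(integer(0), ncol = dims)
      break
    }
    parent_side <- side
  }

  suit <- logical(prod(extent))
  if (nrow(origins) > 0) {
    stride <- cumprod(c(1, extent[-dims]))
    lin <- as.vector(origins %*% stride) + 1
    suit[lin] <- TRUE
  }
  dim(suit) <- extent
  new_binary_landscape(suit, seed = seed, model = "curdling")
}

#' Binarise a continuous landscape by rank
#'
#' Classifies the `k` highest-valued cells of a continuous landscape as
#' suitable.  Ties at the cut are broken by flattened (column-major) cell
#' index, a stable, documented order; with continuous fBm values ties have
#' probability zero in practice.
#'
#' @param land an `fbm_landscape`.
#' @param k number of suitable cells, in `[0, N]`; alternatively supply
#'   `h` to request `round(h * N)`.
#' @param h optional proportion, used when `k` is missing.
#' @return an `fbm_binary_landscape`.
#' @examples
#' land <- fbm_landscape(32, hurst = 0.2, seed = 7)
#' threshold_by_rank(land, h = 0.28)
#' @export
threshold_by_rank <- function(land, k = NULL, h = NULL) {
  stopifnot(is_landscape(land))
  n_cells <- prod(land$extent)
  if (is.null(k)) {
    if (is.null(h)) stop("supply either `k` or `h`")
    if (h < 0 || h > 1) stop("`h` must lie in [0, 1]")
    k <- round(h * n_cells)
  }
  if (k != round(k) || k < 0 || k > n_cells)
    stop("`k` must be an integer in [0, ", n_cells, "]")
  v <- as.vector(land$values)
  suit <- rank(-v, ties.method = "first") <= k
  dim(suit) <- land$extent
  new_binary_landscape(suit, seed = land$seed, model = "rank_threshold")
}

check_extent <- function(extent) {
  if (!is.numeric(extent) || length(extent) < 1L || anyNA(extent) ||
      any(extent < 1) || any(extent != round(extent)))
    stop("`extent` must be a vector of positive integers")
  as.integer(extent)
}
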