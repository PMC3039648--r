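#' Design a replicated anisotropy experiment
#'
#' Defines the factorial Monte Carlo design used to compare the two spectral
#' synthesis algorithms: every (algorithm, Hurst exponent) combination is
#' replicated `replicates` times on an `n x n` lattice.  The default design
#' -- both algorithms, H in \{0.1, 0.5, 0.9\}, 100 replicates, 32 x 32 cells
#' -- generates 600 landscapes in total.
#'
#' Replicate `r` of combination `c` (combinations ordered algorithm-major,
#' Hurst exponents within) uses seed `base_seed + c * 10^6 + r`, so any
#' single landscape can be regenerated in isolation.
#'
#' @param algorithms subset of `c(1, 2)`.
#' @param hurst_levels Hurst exponents to test, each in (0, 1).
#' @param replicates landscapes per combination.
#' @param n lattice side length (power of two).
#' @param base_seed integer base seed.
#' @return an `experiment_design` object.
#' @export
experiment_design <- function(algorithms = c(1, 2),
                              hurst_levels = c(0.1, 0.5, 0.9),
                              replicates = 100, n = 32, base_seed = 1) {
  stopifnot(all(algorithms %in% c(1, 2)), length(algorithms) >= 1,
            replicates >= 1)
  check_side_length(n)
  for (h in hurst_levels) check_hurst(h, 1L)
  combos <- expand.grid(hurst = hurst_levels, algorithm = algorithms)
  combos <- combos[order(combos$algorithm, combos$hurst), c(2, 1)]
  combos$combination <- seq_len(nrow(combos))
  structure(list(combinations = tibble::as_tibble(combos),
                 replicates = as.integer(replicates), n = as.integer(n),
                 base_seed = as.integer(base_seed)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design> ", nrow(x$combinations), " combinations x ",
      x$replicates, " replicates on ", x$n, " x ", x$n, " lattices (",
      nrow(x$combinations) * x$replicates, " landscapes), base seed ",
      x$base_seed, "\n", sep = "")
  invisible(x)
}

replicate_seed <- function(design, combination, replicate) {
  design$base_seed + combination * 1000000L + replicate
}

#' Run the replicated anisotropy experiment
#'
#' For every replicate of every (algorithm, Hurst) combination: generate the
#' landscape, compute the four directional Moran's I correlograms on the
#' torus, and reduce them to the two perpendicular difference statistics
#' (see [delta_statistics()]).  Replicate-level differences are kept, and a
#' per-combination summary gives for each distance class and statistic the
#' median, type-7 quartiles, full range, and the McGill notch half-width
#' `1.58 * IQR / sqrt(m)` -- a rough 95% confidence interval for the median.
#' The run is deterministic given the design's base seed.
#'
#' @param design an [experiment_design()].
#' @param max_distance largest distance class summarised (default `n/2`).
#' @return an `fbm_experiment` object with elements `design`, `replicates`
#'   (tibble: algorithm, hurst, replicate, distance, delta_cardinal,
#'   delta_diagonal) and `summary` (tidy tibble, one row per combination x
#'   statistic x distance).
#' @examples
#' \donttest{
#' res <- run_experiment(experiment_design(replicates = 5, n = 16))
#' tidy(res)
#' }
#' @export
run_experiment <- function(design, max_distance = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  n <- design$n
  if (is.null(max_distance)) max_distance <- n %/% 2
  dists <- seq_len(max_distance)
  nets <- lapply(c(0, 45, 90, 135), function(th) build_network(n, th))

  combos <- design$combinations
  rep_rows <- vector("list", nrow(combos) * design$replicates)
  idx <- 0L
  for (ci in seq_len(nrow(combos))) {
    alg <- combos$algorithm[ci]
    h <- combos$hurst[ci]
    for (r in seq_len(design$replicates)) {
      seed <- replicate_seed(design, combos$combination[ci], r)
      land <- fbm_landscape(n, dims = 2, hurst = h, seed = seed,
                            algorithm = alg)
      im <- all_directional_i(land$values, nets, dists)
      idx <- idx + 1L
      rep_rows[[idx]] <- tibble::tibble(
        algorithm = alg, hurst = h, replicate = r, distance = dists,
        delta_cardinal = im[, 1] - im[, 3],
        delta_diagonal = im[, 2] - im[, 4])
    }
  }
  reps <- dplyr::bind_rows(rep_rows)

  long <- deltas_long(reps)
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$algorithm, .data$hurst, .data$statistic,
                    .data$distance),
    m = dplyr::n(),
    median = median(.data$delta),
    q1 = quantile(.data$delta, 0.25, type = 7, names = FALSE),
    q3 = quantile(.data$delta, 0.75, type = 7, names = FALSE),
    min = min(.data$delta),
    max = max(.data$delta),
    .groups = "drop")
  summ$notch_half_width <- 1.58 * (summ$q3 - summ$q1) / sqrt(summ$m)
  summ$notch_lo <- summ$median - summ$notch_half_width
  summ$notch_hi <- summ$median + summ$notch_half_width

  structure(list(design = design, replicates = reps, summary = summ),
            class = "fbm_experiment")
}

# long format: one row per replicate x distance x statistic
deltas_long <- function(reps) {
  base <- reps[c("algorithm", "hurst", "replicate", "distance")]
  dplyr::bind_rows(
    dplyr::mutate(base, statistic = "cardinal", delta = reps$delta_cardinal),
    dplyr::mutate(base, statistic = "diagonal", delta = reps$delta_diagonal))
}

#' @export
print.fbm_experiment <- function(x, ...) {
  d <- x$design
  cat("<fbm_experiment> ", nrow(d$combinations) * d$replicates,
      " landscapes (", nrow(d$combinations), " combinations x ",
      d$replicates, " replicates, ", d$n, " x ", d$n, ")\n", sep = "")
  cat("  summary rows: ", nrow(x$summary), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.fbm_experiment <- function(x, ...) x$summary

#' @export
glance.fbm_experiment <- function(x, ...) {
  d <- x$design
  tibble::tibble(
    n_landscapes = nrow(d$combinations) * d$replicates,
    n_combinations = nrow(d$combinations),
    replicates = d$replicates,
    side_length = d$n,
    base_seed = d$base_seed,
    max_distance = max(x$summary$distance))
}

#' McGill notch interval for a replicate sample
#'
#' Median with a rough 95% confidence interval based on asymptotic
#' normality: `median +/- 1.58 * IQR / sqrt(m)`, the Tukey boxplot notch
#' convention.  Quartiles use linear interpolation of order statistics
#' (type 7, R's default).
#'
#' @param values numeric replicate sample (non-empty).
#' @param constant notch multiplier (default 1.58).
#' @return named numeric vector `c(median, lower, upper)`.
#' @examples
#' notch_interval(1:100)  # half-width 1.58 * 49.5 / 10
#' @export
notch_interval <- function(values, constant = 1.58) {
  if (length(values) == 0) stop("`values` must be non-empty")
  if (anyNA(values)) stop("`values` must not contain NA")
  med <- median(values)
  iqr <- quantile(values, 0.75, type = 7, names = FALSE) -
    quantile(values, 0.25, type = 7, names = FALSE)
  half <- constant * iqr / sqrt(length(values))
  c(median = med, lower = med - half, upper = med + half)
}

#' Box plots of the anisotropy difference statistics
#'
#' Mirrors the classic presentation of the replicated experiment: notched
#' box plots of one difference statistic per distance class, algorithms side
#' by side, faceted by Hurst exponent.  The notches are
#' `+/- 1.58 * IQR / sqrt(m)`; the whiskers span the full range.
#'
#' @param object an `fbm_experiment`.
#' @param statistic `"cardinal"` or `"diagonal"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fbm_experiment <- function(object, statistic = c("cardinal",
                                                          "diagonal"), ...) {
  statistic <- match.arg(statistic)
  reps <- object$replicates
  reps$delta <- if (statistic == "cardinal") reps$delta_cardinal
                else reps$delta_diagonal
  ggplot2::ggplot(reps,
      ggplot2::aes(x = factor(.data$distance), y = .data$delta,
                   fill = factor(.data$algorithm))) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "red") +
    ggplot2::geom_boxplot(notch = TRUE, coef = Inf,
                          position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::facet_wrap(~hurst, ncol = 1, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "distance class (link hops)",
                  y = paste0("delta Moran's I (", statistic, ")"),
                  fill = "algorithm") +
    ggplot2::theme_minimal()
}

#' Export an experiment summary as tidy CSV
#'
#' @param x an `fbm_experiment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(x, path) {
  stopifnot(inherits(x, "fbm_experiment"))
  utils::write.csv(x$summary, path, row.names = FALSE)
  invisible(path)
}
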