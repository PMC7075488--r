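# Monte Carlo engine: factorial design over loading patterns, latent
# correlations and sample sizes; per-replicate evaluation of the original
# criterion (via CFA) and the manifest criterion (double / single
# correction); aggregation into detection-rate tables.

#' The six loading patterns of the default simulation design
#'
#' One essentially tau-equivalent pattern (all loadings 0.70) and five
#' congeneric patterns of increasing heterogeneity, mirrored across the two
#' factors; all patterns share a mean loading of 0.70.
#'
#' @return A named list of length 6; each element is the loading vector
#'   used for both factors.
#' @export
default_loading_patterns <- function() {
  list(p1 = c(0.70, 0.70, 0.70),
       p2 = c(0.65, 0.70, 0.75),
       p3 = c(0.60, 0.70, 0.80),
       p4 = c(0.55, 0.70, 0.85),
       p5 = c(0.50, 0.70, 0.90),
       p6 = c(0.45, 0.70, 0.95))
}

#' Configuration of the Monte Carlo study
#'
#' Defaults reproduce the full published design: 6 loading patterns x
#' 51 latent correlations (1.00 down to 0.00 in steps of 0.02) x sample
#' sizes {250, 1000} x 1,000 replicates = 612 cells, 612,000 runs.
#' The grid is stored as integers in hundredths to keep cell labels free
#' of floating-point drift.
#'
#' @param loading_patterns Named list of loading vectors (used for both
#'   factors of each model). Default [default_loading_patterns()].
#' @param phi_grid_hundredths Integer vector of latent correlations in
#'   hundredths, each in 0..100. Default `seq(100, 0, by = -2)`.
#' @param sample_sizes Integer vector of sample sizes.
#' @param n_reps Replicates per design cell.
#' @param base_seed Integer master seed; every replicate's seed derives
#'   deterministically from it and the cell coordinates.
#'
#' @return An object of class `"simulation_config"`.
#' @examples
#' cfg <- simulation_config()
#' n_cells(cfg)       # 612
#' n_replicates(cfg)  # 612000
#' @export
simulation_config <- function(loading_patterns = default_loading_patterns(),
                              phi_grid_hundredths = seq(100L, 0L, by = -2L),
                              sample_sizes = c(250L, 1000L),
                              n_reps = 1000L,
                              base_seed = 20200223L) {
  stopifnot(length(loading_patterns) >= 1L,
            all(vapply(loading_patterns, length, integer(1)) >= 2L))
  phi_h <- as.integer(phi_grid_hundredths)
  if (any(is.na(phi_h)) || any(phi_h < 0L) || any(phi_h > 100L)) {
    stop("phi_grid_hundredths must be integers in 0..100", call. = FALSE)
  }
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (is.null(names(loading_patterns))) {
    names(loading_patterns) <- paste0("p", seq_along(loading_patterns))
  }
  structure(list(loading_patterns = loading_patterns,
                 phi_grid_hundredths = phi_h,
                 sample_sizes = as.integer(sample_sizes),
                 n_reps = as.integer(n_reps),
                 base_seed = as.integer(base_seed)),
            class = "simulation_config")
}

#' Number of design cells / total replicates of a configuration
#'
#' @param config A [simulation_config()].
#' @return Integer count.
#' @export
n_cells <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  length(config$loading_patterns) * length(config$phi_grid_hundredths) *
    length(config$sample_sizes)
}

#' @rdname n_cells
#' @export
n_replicates <- function(config) {
  n_cells(config) * config$n_reps
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> %d patterns x %d phi x %d n x %d",
                     " reps = %d cells, %d runs (seed %d)\n"),
              length(x$loading_patterns), length(x$phi_grid_hundredths),
              length(x$sample_sizes), x$n_reps, n_cells(x), n_replicates(x),
              x$base_seed))
  invisible(x)
}

#' Deterministic per-replicate seed
#'
#' Mixes the master seed with the cell coordinates (pattern, grid point,
#' sample size, replicate) into a seed below 2^31, so any single cell or
#' replicate of a study is reproducible in isolation.
#'
#' @param base_seed Master integer seed.
#' @param pattern_idx,phi_idx,n_idx,rep_idx 1-based cell coordinates.
#' @return An integer seed.
#' @export
replicate_seed <- function(base_seed, pattern_idx, phi_idx, n_idx, rep_idx) {
  m <- 2147483629
  h <- (base_seed %% m)
  for (k in c(pattern_idx, phi_idx, n_idx, rep_idx)) {
    h <- (h * 48271 + k + 1) %% m
  }
  as.integer(h)
}

#' Evaluate all three criteria on one simulated dataset
#'
#' Draws one sample from the model and evaluates (a) the original
#' Fornell-Larcker criterion from a CFA fit (AVEs of the standardized
#' solution and the estimated latent correlation), and (b) the manifest
#' criterion with double and single correction from the sample standardized
#' alphas of the two item blocks and the sample composite-score
#' correlation. Composites are unweighted item means.
#'
#' @param model A [factor_model()].
#' @param n Sample size.
#' @param seed Integer seed for this replicate.
#' @return A list: `ofl_met`, `double_met`, `single_met` (logicals; oFL is
#'   `NA` when the CFA did not converge), `converged`, plus the sample
#'   quantities `alpha_x`, `alpha_y`, `r_composite`, `phi_hat`.
#' @export
run_replicate <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "factor_model"))
  dat <- sample_dataset(model, n, seed = seed)
  kx <- length(model$loadings_x)
  p <- ncol(dat)
  r_all <- stats::cor(dat)
  rx <- r_all[1:kx, 1:kx, drop = FALSE]
  ry <- r_all[(kx + 1):p, (kx + 1):p, drop = FALSE]
  alpha_x <- standardized_alpha(rx)
  alpha_y <- standardized_alpha(ry)
  r_comp <- stats::cor(rowMeans(dat[, 1:kx, drop = FALSE]),
                       rowMeans(dat[, (kx + 1):p, drop = FALSE]))

  mfl_ok <- alpha_x > 0 && alpha_x <= 1 && alpha_y > 0 && alpha_y <= 1
  if (mfl_ok) {
    dim_x <- dimension_summary("x", alpha_x, kx)
    dim_y <- dimension_summary("y", alpha_y, p - kx)
    double_met <- mfl_pair(dim_x, dim_y, r_comp, "double")
    single_met <- mfl_pair(dim_x, dim_y, r_comp, "single")
  } else {
    double_met <- single_met <- NA  # degenerate sample alpha
  }

  fit <- fit_cfa(dat, n_per_factor = c(kx, p - kx))
  if (fit$converged) {
    ofl_met <- ofl_pair(ave_from_loadings(fit$loadings_x),
                        ave_from_loadings(fit$loadings_y),
                        max(-1, min(1, fit$phi)))
  } else {
    ofl_met <- NA
  }
  list(ofl_met = ofl_met, double_met = double_met, single_met = single_met,
       converged = fit$converged,
       alpha_x = alpha_x, alpha_y = alpha_y,
       r_composite = r_comp, phi_hat = fit$phi)
}

#' Run the full factorial Monte Carlo grid
#'
#' Iterates every pattern x phi x sample-size cell of the configuration,
#' runs `n_reps` replicates per cell with deterministic per-replicate
#' seeds, and aggregates the percentage of replicates in which each
#' criterion indicates that distinctiveness is met. Non-convergent CFA
#' replicates are excluded from the oFL denominator only; the manifest
#' criterion needs no fitting and uses all replicates.
#'
#' @param config A [simulation_config()].
#' @param progress Print a line per cell.
#' @return A data.frame of class `"cell_results"`, one row per cell:
#'   `pattern_id`, `phi` (numeric), `n`, `n_reps`, `n_converged`,
#'   `met_rate_ofl`, `met_rate_double`, `met_rate_single` (percentages).
#' @export
run_grid <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  rows <- vector("list", n_cells(config))
  idx <- 0L
  for (pi in seq_along(config$loading_patterns)) {
    lam <- config$loading_patterns[[pi]]
    pid <- names(config$loading_patterns)[pi]
    for (gi in seq_along(config$phi_grid_hundredths)) {
      phi_h <- config$phi_grid_hundredths[gi]
      model <- factor_model(lam, lam, phi_h / 100)
      for (ni in seq_along(config$sample_sizes)) {
        n <- config$sample_sizes[ni]
        ofl <- dbl <- sgl <- logical(0)
        conv <- 0L
        for (r in seq_len(config$n_reps)) {
          s <- replicate_seed(config$base_seed, pi, gi, ni, r)
          rep_out <- run_replicate(model, n, seed = s)
          if (isTRUE(rep_out$converged)) {
            conv <- conv + 1L
            ofl <- c(ofl, rep_out$ofl_met)
          }
          dbl <- c(dbl, rep_out$double_met)
          sgl <- c(sgl, rep_out$single_met)
        }
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          pattern_id = pid, phi = phi_h / 100, n = n,
          n_reps = config$n_reps, n_converged = conv,
          met_rate_ofl = 100 * mean(ofl, na.rm = TRUE),
          met_rate_double = 100 * mean(dbl, na.rm = TRUE),
          met_rate_single = 100 * mean(sgl, na.rm = TRUE),
          stringsAsFactors = FALSE)
        if (progress) {
          cat(sprintf("cell %s phi=%.2f n=%d: ofl %.1f dbl %.1f sgl %.1f\n",
                      pid, phi_h / 100, n, rows[[idx]]$met_rate_ofl,
                      rows[[idx]]$met_rate_double,
                      rows[[idx]]$met_rate_single))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cell_results", "data.frame")
  out
}

#' Noise-free population decision curves for one loading pattern
#'
#' Evaluates all three criteria on population quantities at each grid
#' point: the original criterion from the true AVEs and phi; the manifest
#' criterion from the population standardized alphas (implied inter-item
#' correlations) and the population composite-score correlation.
#'
#' @param loadings Loading vector used for both factors.
#' @param phi_grid_hundredths Integer grid of latent correlations in
#'   hundredths. Default the full 51-point grid.
#' @return A data.frame: `phi`, `ofl_met`, `double_met`, `single_met`.
#' @examples
#' pc <- population_decision_curve(c(0.7, 0.7, 0.7))
#' pc[pc$phi >= 0.68 & pc$phi <= 0.74, ]
#' @export
population_decision_curve <- function(loadings,
                                      phi_grid_hundredths =
                                        seq(100L, 0L, by = -2L)) {
  lam <- as.numeric(loadings)
  k <- length(lam)
  ave_true <- ave_from_loadings(lam)
  rows <- lapply(as.integer(phi_grid_hundredths), function(phi_h) {
    phi <- phi_h / 100
    model <- factor_model(lam, lam, phi)
    alphas <- population_alphas(model)
    r_pop <- population_composite_correlation(model)
    dim_x <- dimension_summary("x", alphas[1], k)
    dim_y <- dimension_summary("y", alphas[2], k)
    data.frame(phi = phi,
               ofl_met = ofl_pair(ave_true, ave_true, phi),
               double_met = mfl_pair(dim_x, dim_y, r_pop, "double"),
               single_met = mfl_pair(dim_x, dim_y, r_pop, "single"))
  })
  do.call(rbind, rows)
}
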