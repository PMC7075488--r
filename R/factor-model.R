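# Population two-factor measurement model: implied correlation structure,
# composite-score correlation, and multivariate-normal data generation.

#' Population two-factor measurement model
#'
#' A standardized two-factor model: each indicator loads on exactly one of
#' two latent variables with standardized loading `lambda`, unique variance
#' `1 - lambda^2`, and the factors correlate at `phi`.
#'
#' @param loadings_x,loadings_y Standardized loadings of the indicators of
#'   each factor (length >= 2, each in (-1, 1]).
#' @param phi Latent correlation, in \[-1, 1\].
#'
#' @return An object of class `"factor_model"` with fields `loadings_x`,
#'   `loadings_y`, `phi`, `error_variances` (per indicator, `1 - lambda^2`).
#' @examples
#' factor_model(rep(0.7, 3), rep(0.7, 3), phi = 0.6)
#' @export
factor_model <- function(loadings_x, loadings_y, phi) {
  lx <- as.numeric(loadings_x); ly <- as.numeric(loadings_y)
  for (l in list(lx, ly)) {
    if (length(l) < 2L || any(is.na(l)) || any(l <= -1) ||
        any(l > 1 + 1e-12)) {
      stop("loadings must be vectors of length >= 2 with entries in (-1, 1]",
           call. = FALSE)
    }
  }
  if (is.na(phi) || abs(phi) > 1 + 1e-12) {
    stop("|phi| must be <= 1", call. = FALSE)
  }
  structure(list(loadings_x = lx, loadings_y = ly, phi = as.numeric(phi),
                 error_variances = 1 - c(lx, ly)^2),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> phi = %.3f\n  lambda_x: %s\n  lambda_y: %s\n",
              x$phi, paste(format(x$loadings_x), collapse = " "),
              paste(format(x$loadings_y), collapse = " ")))
  invisible(x)
}

#' Model-implied indicator correlation matrix
#'
#' Within a factor, indicators i and j correlate at `lambda_i * lambda_j`;
#' across factors at `lambda_i * phi * lambda_j`; the diagonal is 1
#' (standardized indicators).
#'
#' @param model A [factor_model()].
#' @return The (Kx + Ky) x (Kx + Ky) implied correlation matrix.
#' @examples
#' implied_correlation_matrix(factor_model(rep(0.7, 3), rep(0.7, 3), 0.6))
#' @export
implied_correlation_matrix <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  lam <- c(model$loadings_x, model$loadings_y)
  kx <- length(model$loadings_x)
  p <- length(lam)
  fac <- rep(1:2, c(kx, p - kx))
  phi_mat <- matrix(c(1, model$phi, model$phi, 1), 2, 2)
  sigma <- outer(lam, lam) * phi_mat[fac, fac]
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("implied correlation matrix is not positive semi-definite ",
         "(invalid loadings/phi combination)", call. = FALSE)
  }
  sigma
}

#' Population correlation between the two composite scores
#'
#' Closed-form correlation between the unweighted item means of the two
#' indicator blocks under the model:
#' `phi * sum(lx) * sum(ly) / sqrt(var_x * var_y)` with
#' `var_x = Kx + sum_{i != j} lx_i * lx_j` (likewise for y).
#'
#' @param model A [factor_model()].
#' @return The population composite-score correlation.
#' @examples
#' population_composite_correlation(
#'   factor_model(rep(0.7, 3), rep(0.7, 3), 0.6))  # 0.6 * 4.41 / 5.94
#' @export
population_composite_correlation <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  lx <- model$loadings_x; ly <- model$loadings_y
  vx <- length(lx) + sum(outer(lx, lx)) - sum(lx^2)
  vy <- length(ly) + sum(outer(ly, ly)) - sum(ly^2)
  model$phi * sum(lx) * sum(ly) / sqrt(vx * vy)
}

#' Population standardized alphas of the two blocks
#'
#' Standardized Cronbach's alpha evaluated on the model-implied inter-item
#' correlations of each indicator block.
#'
#' @param model A [factor_model()].
#' @return Numeric vector `c(alpha_x, alpha_y)`.
#' @export
population_alphas <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  sigma <- implied_correlation_matrix(model)
  kx <- length(model$loadings_x)
  p <- nrow(sigma)
  c(standardized_alpha(sigma[1:kx, 1:kx, drop = FALSE]),
    standardized_alpha(sigma[(kx + 1):p, (kx + 1):p, drop = FALSE]))
}

#' Draw a sample from the model
#'
#' Generates `n` independent multivariate-normal observations with mean zero
#' and covariance equal to the model-implied correlation matrix.
#' Reproducible given `seed`.
#'
#' @param model A [factor_model()].
#' @param n Sample size (>= 10).
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return An `n x (Kx + Ky)` data matrix, columns `x1..xK, y1..yK`.
#' @export
sample_dataset <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "factor_model"))
  if (n < 10) stop("n must be >= 10", call. = FALSE)
  sigma <- implied_correlation_matrix(model)
  if (!is.null(seed)) set.seed(seed)
  x <- MASS::mvrnorm(n, mu = rep(0, nrow(sigma)), Sigma = sigma)
  kx <- length(model$loadings_x)
  colnames(x) <- c(paste0("x", seq_len(kx)),
                   paste0("y", seq_len(nrow(sigma) - kx)))
  x
}
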