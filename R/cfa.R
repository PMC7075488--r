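# Maximum-likelihood confirmatory factor analysis for the two-factor
# measurement model. Minimizes the normal-theory discrepancy
#   F = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p
# over loadings, the latent correlation and unique variances, with both
# factor variances fixed at 1 (all loadings free).

# Discrepancy and its analytic gradient for a simple-structure model:
# theta = (lambda_1..lambda_p, phi, psi_1..psi_p), indicator i loads on
# factor fac[i] only. Gradient: with G = Sigma^-1 (Sigma - S) Sigma^-1,
#   dF/dLambda = 2 G Lambda Phi (structured entries),
#   dF/dphi    = 2 (Lambda' G Lambda)[1,2],
#   dF/dpsi_i  = G[i,i].
.cfa_sigma <- function(theta, fac, n_ind) {
  lam <- theta[1:n_ind]
  phi <- theta[n_ind + 1L]
  psi <- theta[(n_ind + 2L):(2L * n_ind + 1L)]
  phi_mat <- matrix(c(1, phi, phi, 1), 2, 2)
  sigma <- outer(lam, lam) * phi_mat[fac, fac]
  diag(sigma) <- lam^2 + psi
  sigma
}

.cfa_objective <- function(theta, s_mat, log_det_s, fac, n_ind) {
  sigma <- .cfa_sigma(theta, fac, n_ind)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  log_det <- 2 * sum(log(diag(ch)))
  sinv_s <- chol2inv(ch) %*% s_mat
  f <- log_det + sum(diag(sinv_s)) - log_det_s - n_ind
  if (!is.finite(f)) 1e10 else f
}

.cfa_gradient <- function(theta, s_mat, log_det_s, fac, n_ind) {
  sigma <- .cfa_sigma(theta, fac, n_ind)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(rep(0, length(theta)))
  sigma_inv <- chol2inv(ch)
  g <- sigma_inv %*% (sigma - s_mat) %*% sigma_inv
  lam <- theta[1:n_ind]
  phi <- theta[n_ind + 1L]
  lambda_mat <- matrix(0, n_ind, 2)
  lambda_mat[cbind(seq_len(n_ind), fac)] <- lam
  phi_mat <- matrix(c(1, phi, phi, 1), 2, 2)
  d_lambda <- 2 * (g %*% lambda_mat %*% phi_mat)
  lgl <- t(lambda_mat) %*% g %*% lambda_mat
  c(d_lambda[cbind(seq_len(n_ind), fac)], 2 * lgl[1, 2], diag(g))
}

#' Fit the two-factor CFA by maximum likelihood
#'
#' Estimates loadings, the latent correlation and unique variances from a
#' sample correlation (or covariance) matrix by minimizing the ML
#' discrepancy with `stats::optim` (L-BFGS-B, analytic gradient). Factor
#' variances are fixed at 1 and all loadings are free. Completely
#' standardized loadings `lambda_i / sqrt(lambda_i^2 + psi_i)` are reported
#' so AVE can be computed on the standardized solution. Unique variances
#' are bounded below at 1e-6; fits resting on that bound (Heywood cases)
#' are flagged but retained. On non-convergence the fit is retried from
#' jittered start values.
#'
#' @param data Either an `n x p` data matrix (its correlation matrix is
#'   used) or, with `is_corr = TRUE`, a `p x p` correlation matrix treated
#'   directly as the sample matrix S.
#' @param n_per_factor Integer vector of length 2: number of indicators
#'   assigned to each factor, in column order. Default `c(3, 3)`.
#' @param is_corr Set `TRUE` when `data` is already a correlation matrix.
#' @param max_restarts Maximum jittered restarts after a failed fit.
#' @param seed Optional seed controlling the restart jitter.
#'
#' @return An object of class `"cfa_fit"`: `loadings_x`, `loadings_y`
#'   (standardized), `phi`, `error_variances`, `discrepancy`, `converged`,
#'   `heywood`, `n_restarts_used`.
#' @examples
#' m <- factor_model(c(0.6, 0.7, 0.8), c(0.6, 0.7, 0.8), 0.6)
#' fit <- fit_cfa(implied_correlation_matrix(m), is_corr = TRUE)
#' fit$phi
#' @export
fit_cfa <- function(data, n_per_factor = c(3L, 3L), is_corr = FALSE,
                    max_restarts = 5L, seed = NULL) {
  if (any(n_per_factor < 2L)) {
    stop("each factor needs >= 2 indicators", call. = FALSE)
  }
  p <- sum(n_per_factor)
  if (is_corr) {
    s_mat <- as.matrix(data)
    if (nrow(s_mat) != p || ncol(s_mat) != p) {
      stop("correlation matrix must be ", p, " x ", p, call. = FALSE)
    }
  } else {
    s_mat <- stats::cor(as.matrix(data))
    if (ncol(s_mat) != p) {
      stop("data must have ", p, " columns to match n_per_factor",
           call. = FALSE)
    }
  }
  det_s <- det(s_mat)
  if (!is.finite(det_s) || det_s <= 1e-12) {
    stop("sample matrix is (near-)singular; the ML discrepancy is undefined",
         call. = FALSE)
  }
  log_det_s <- log(det_s)
  fac <- rep(1:2, n_per_factor)

  start <- c(rep(0.7, p), 0.3, rep(0.5, p))
  lower <- c(rep(-1.5, p), -0.995, rep(1e-6, p))
  upper <- c(rep(1.5, p), 0.995, rep(2, p))
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  n_restarts_used <- 0L
  for (attempt in 0:max_restarts) {
    th0 <- if (attempt == 0L) start else {
      pmin(pmax(start + stats::runif(length(start), -0.2, 0.2), lower + 1e-4),
           upper - 1e-4)
    }
    res <- tryCatch(
      stats::optim(th0, .cfa_objective, .cfa_gradient,
                   s_mat = s_mat, log_det_s = log_det_s, fac = fac, n_ind = p,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL)
    ok <- !is.null(res) && res$convergence == 0L && is.finite(res$value) &&
      res$value < 1e9
    if (ok && (is.null(best) || res$value < best$value)) best <- res
    if (ok && attempt == 0L) break
    if (ok && !is.null(best)) break
    n_restarts_used <- attempt + 1L
    if (n_restarts_used > max_restarts) break
  }

  if (is.null(best)) {
    return(structure(list(
      loadings_x = rep(NA_real_, n_per_factor[1]),
      loadings_y = rep(NA_real_, n_per_factor[2]),
      phi = NA_real_, error_variances = rep(NA_real_, p),
      discrepancy = NA_real_, converged = FALSE, heywood = FALSE,
      n_restarts_used = n_restarts_used), class = "cfa_fit"))
  }

  th <- best$par
  lam_raw <- th[1:p]
  psi <- th[(p + 2L):(2L * p + 1L)]
  lam_std <- lam_raw / sqrt(lam_raw^2 + psi)
  phi_hat <- th[p + 1L]
  structure(list(
    loadings_x = lam_std[fac == 1L],
    loadings_y = lam_std[fac == 2L],
    phi = phi_hat,
    error_variances = 1 - lam_std^2,
    discrepancy = best$value,
    converged = TRUE,
    heywood = any(psi <= 1e-6 + 1e-10),
    n_restarts_used = n_restarts_used), class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("<cfa_fit> %s, F = %.3e, phi = %.4f%s\n",
              if (x$converged) "converged" else "NOT converged",
              x$discrepancy, x$phi,
              if (isTRUE(x$heywood)) " [Heywood]" else ""))
  cat("  std loadings x:", paste(sprintf("%.4f", x$loadings_x),
                                 collapse = " "), "\n")
  cat("  std loadings y:", paste(sprintf("%.4f", x$loadings_y),
                                 collapse = " "), "\n")
  invisible(x)
}
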