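# Closed-form distinctiveness criteria: average variance extracted (AVE),
# standardized Cronbach's alpha, correction for attenuation, and the
# original / manifest Fornell-Larcker decisions.

# Numerical tolerance for the AVE-vs-squared-correlation comparisons.
# Exact ties (a measure-zero event, but one the default simulation grid hits
# at phi = 0.70 for the tau-equivalent pattern, where AVE = phi^2 = 0.49)
# resolve as "met": the violation region is the open set {rhat^2 > AVE}.
# Without a tolerance the decision at such a tie is round-off path-dependent.
.fl_tol <- 1e-10

.fl_met <- function(ave, rhat_sq) {
  (ave - rhat_sq) >= -.fl_tol
}

#' Summary of one instrument dimension
#'
#' Bundles the reliability information the manifest Fornell-Larcker criterion
#' needs about a single dimension (subscale) of a multidimensional
#' instrument: its Cronbach's alpha and its number of items.
#'
#' @param name Dimension identifier (single string).
#' @param alpha Cronbach's alpha of the dimension, in (0, 1].
#' @param n_items Number of items (indicators), at least 2; alpha is
#'   undefined for a single item.
#'
#' @return An object of class `"dimension_summary"`.
#' @examples
#' dimension_summary("anxiety", alpha = 0.85, n_items = 6)
#' @export
dimension_summary <- function(name, alpha, n_items) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("alpha must be a single value in (0, 1]; dimension '", name,
         "' has alpha = ", format(alpha), call. = FALSE)
  }
  if (!is.numeric(n_items) || length(n_items) != 1L || is.na(n_items) ||
      n_items < 2 || n_items != round(n_items)) {
    stop("n_items must be an integer >= 2; dimension '", name,
         "' has n_items = ", format(n_items), call. = FALSE)
  }
  structure(list(name = name, alpha = as.numeric(alpha),
                 n_items = as.integer(n_items)),
            class = "dimension_summary")
}

#' @export
print.dimension_summary <- function(x, ...) {
  cat(sprintf("<dimension> %s: alpha = %.4f, K = %d\n",
              x$name, x$alpha, x$n_items))
  invisible(x)
}

#' Summary of a multidimensional instrument
#'
#' Holds everything the manifest Fornell-Larcker criterion consumes: the
#' per-dimension reliability summaries and the correlation matrix between
#' the manifest composite scores (unweighted item means) of the dimensions.
#'
#' @param dimensions List of [dimension_summary()] objects (ordered).
#' @param composite_corr Square symmetric correlation matrix with unit
#'   diagonal; row/column i corresponds to `dimensions[[i]]`.
#'
#' @return An object of class `"instrument_summary"`.
#' @examples
#' instrument_summary(
#'   list(dimension_summary("A", 0.8, 4), dimension_summary("B", 0.7, 5)),
#'   composite_corr = matrix(c(1, 0.4, 0.4, 1), 2, 2)
#' )
#' @export
instrument_summary <- function(dimensions, composite_corr) {
  if (!is.list(dimensions) || length(dimensions) < 2L ||
      !all(vapply(dimensions, inherits, logical(1), "dimension_summary"))) {
    stop("dimensions must be a list of >= 2 dimension_summary objects",
         call. = FALSE)
  }
  d <- length(dimensions)
  r <- as.matrix(composite_corr)
  if (nrow(r) != d || ncol(r) != d) {
    stop("composite_corr must be ", d, " x ", d, " to match the ", d,
         " dimensions; got ", nrow(r), " x ", ncol(r), call. = FALSE)
  }
  if (any(is.na(r)) || any(abs(r) > 1 + 1e-12)) {
    stop("composite_corr entries must lie in [-1, 1]", call. = FALSE)
  }
  if (any(abs(diag(r) - 1) > 1e-8)) {
    stop("composite_corr must have a unit diagonal", call. = FALSE)
  }
  if (any(abs(r - t(r)) > 1e-6)) {
    bad <- which(abs(r - t(r)) > 1e-6, arr.ind = TRUE)
    stop("composite_corr is asymmetric at entries: ",
         paste(apply(bad, 1L, paste, collapse = ","), collapse = "; "),
         call. = FALSE)
  }
  r <- (r + t(r)) / 2  # symmetrize after validation
  diag(r) <- 1
  nms <- vapply(dimensions, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("dimension names must be unique", call. = FALSE)
  dimnames(r) <- list(nms, nms)
  structure(list(dimensions = dimensions, composite_corr = r),
            class = "instrument_summary")
}

#' @export
print.instrument_summary <- function(x, ...) {
  cat(sprintf("<instrument> %d dimensions\n", length(x$dimensions)))
  for (d in x$dimensions) {
    cat(sprintf("  %-12s alpha = %.4f  K = %d\n", d$name, d$alpha, d$n_items))
  }
  cat("composite correlations:\n")
  print(round(x$composite_corr, 4))
  invisible(x)
}

#' Standardized Cronbach's alpha from an inter-item correlation matrix
#'
#' Computes the standardized alpha `K * rbar / (1 + (K - 1) * rbar)` where
#' `rbar` is the mean off-diagonal inter-item correlation. Under essential
#' tau-equivalence this equals the reliability of the unweighted composite.
#'
#' @param inter_item_corr Square symmetric correlation matrix (K >= 2 items)
#'   with unit diagonal.
#'
#' @return The standardized alpha (may be negative for negatively
#'   inter-correlated items).
#' @examples
#' r <- matrix(0.49, 3, 3); diag(r) <- 1
#' standardized_alpha(r)  # 1.47 / 1.98 = 0.742424
#' @export
standardized_alpha <- function(inter_item_corr) {
  r <- as.matrix(inter_item_corr)
  k <- nrow(r)
  if (ncol(r) != k || k < 2L) {
    stop("inter_item_corr must be a square matrix with K >= 2 items",
         call. = FALSE)
  }
  if (any(abs(diag(r) - 1) > 1e-8) || any(abs(r - t(r)) > 1e-6)) {
    stop("inter_item_corr must be symmetric with a unit diagonal",
         call. = FALSE)
  }
  rbar <- mean(r[upper.tri(r)])
  denom <- 1 + (k - 1) * rbar
  if (denom <= .fl_tol) {
    stop("mean inter-item correlation ", format(rbar),
         " <= -1/(K-1): standardized alpha is undefined", call. = FALSE)
  }
  k * rbar / denom
}

#' Average variance extracted from standardized loadings
#'
#' `AVE = sum(lambda^2) / K`: the mean share of indicator variance explained
#' by the latent variable, on the completely standardized solution.
#'
#' @param loadings Numeric vector of standardized factor loadings
#'   (length >= 2, each in (-1, 1]).
#'
#' @return The AVE, in (0, 1] for non-degenerate loadings.
#' @examples
#' ave_from_loadings(c(0.7, 0.7, 0.7))      # 0.49
#' ave_from_loadings(c(0.45, 0.70, 0.95))
#' @export
ave_from_loadings <- function(loadings) {
  lam <- as.numeric(loadings)
  if (length(lam) < 2L || any(is.na(lam))) {
    stop("loadings must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (any(lam <= -1) || any(lam > 1 + 1e-12)) {
    stop("standardized loadings must lie in (-1, 1]", call. = FALSE)
  }
  mean(lam^2)
}

#' Average variance extracted from Cronbach's alpha and the item count
#'
#' Inverts the standardized-alpha formula: under essential tau-equivalence
#' `AVE = alpha / (alpha * (1 - K) + K)`, which equals the mean inter-item
#' correlation implied by the alpha.
#'
#' @param alpha Cronbach's alpha, in (0, 1].
#' @param n_items Number of items K (>= 2).
#'
#' @return The alpha-implied AVE.
#' @examples
#' ave_from_alpha(0.742424, 3)  # ~0.49
#' ave_from_alpha(0.9, 4)       # 0.9 / 1.3
#' @export
ave_from_alpha <- function(alpha, n_items) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1 + 1e-12) {
    stop("alpha must be a single value in (0, 1]", call. = FALSE)
  }
  k <- n_items
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k)) {
    stop("n_items must be an integer >= 2", call. = FALSE)
  }
  alpha / (alpha * (1 - k) + k)
}

#' Correct a manifest correlation for attenuation
#'
#' Divides the observed composite-score correlation by the square root of
#' the reliability product (`mode = "double"`, the classical disattenuation)
#' or by the square root of the smaller reliability only
#' (`mode = "single"`, a one-sided correction that underestimates the latent
#' correlation). The result is returned raw — it may exceed 1 in magnitude
#' (overcorrection) and is never clamped.
#'
#' @param r_manifest Observed correlation between the two composites,
#'   in \[-1, 1\].
#' @param alpha_x,alpha_y Reliabilities of the two composites, in (0, 1].
#' @param mode `"double"` or `"single"`.
#'
#' @return The corrected correlation estimate.
#' @examples
#' disattenuate(0.445455, 0.742424, 0.742424, "double")  # ~0.6
#' disattenuate(0.5, 0.9, 0.6, "single")                 # 0.5 / sqrt(0.6)
#' @export
disattenuate <- function(r_manifest, alpha_x, alpha_y,
                         mode = c("double", "single")) {
  mode <- match.arg(mode)
  for (a in c(alpha_x, alpha_y)) {
    if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0 ||
        a > 1 + 1e-12) {
      stop("reliabilities must lie in (0, 1]; division by a zero ",
           "reliability is impossible", call. = FALSE)
    }
  }
  if (abs(r_manifest) > 1 + 1e-12) {
    stop("|r_manifest| must be <= 1", call. = FALSE)
  }
  divisor <- if (mode == "double") sqrt(alpha_x * alpha_y)
             else sqrt(min(alpha_x, alpha_y))
  r_manifest / divisor
}

#' Original Fornell-Larcker decision for one pair of latent variables
#'
#' Distinctiveness is met when each variable's AVE exceeds the squared
#' latent correlation: `ave_x > phi^2 & ave_y > phi^2`. Equality within
#' numerical tolerance resolves as met (see the package vignette).
#'
#' @param ave_x,ave_y Average variance extracted of the two variables,
#'   in (0, 1].
#' @param phi Latent correlation between them, in \[-1, 1\].
#'
#' @return `TRUE` if the criterion is met, `FALSE` if violated.
#' @examples
#' ofl_pair(0.49, 0.49, 0.60)  # TRUE
#' ofl_pair(0.49, 0.49, 0.72)  # FALSE
#' @export
ofl_pair <- function(ave_x, ave_y, phi) {
  for (a in c(ave_x, ave_y)) {
    if (is.na(a) || a <= 0 || a > 1 + 1e-12) {
      stop("AVE values must lie in (0, 1]", call. = FALSE)
    }
  }
  if (is.na(phi) || abs(phi) > 1 + 1e-12) {
    stop("|phi| must be <= 1", call. = FALSE)
  }
  .fl_met(ave_x, phi^2) && .fl_met(ave_y, phi^2)
}

#' Manifest Fornell-Larcker decision for one pair of dimensions
#'
#' Estimates each dimension's AVE from its alpha and item count
#' ([ave_from_alpha()]) and compares both against the squared
#' attenuation-corrected composite correlation: `r^2 / (alpha_x * alpha_y)`
#' for `mode = "double"`, `r^2 / min(alpha_x, alpha_y)` for
#' `mode = "single"`.
#'
#' @param dim_x,dim_y [dimension_summary()] objects.
#' @param r_manifest Observed correlation between the two composite scores.
#' @param mode `"double"` or `"single"`.
#'
#' @return `TRUE` if both AVE inequalities hold, else `FALSE`.
#' @examples
#' a <- dimension_summary("x", 0.742424, 3)
#' mfl_pair(a, a, r_manifest = 0.445455, mode = "double")  # TRUE
#' @export
mfl_pair <- function(dim_x, dim_y, r_manifest,
                     mode = c("double", "single")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dim_x, "dimension_summary"),
            inherits(dim_y, "dimension_summary"))
  ave_x <- ave_from_alpha(dim_x$alpha, dim_x$n_items)
  ave_y <- ave_from_alpha(dim_y$alpha, dim_y$n_items)
  rhat <- disattenuate(r_manifest, dim_x$alpha, dim_y$alpha, mode)
  .fl_met(ave_x, rhat^2) && .fl_met(ave_y, rhat^2)
}

#' Full manifest Fornell-Larcker assessment of one dimension pair
#'
#' Computes alpha-implied AVEs, both corrected correlations, both criterion
#' decisions, and the combined verdict. Because the single correction
#' divides by a larger quantity, its corrected correlation is never larger
#' in magnitude than the double-corrected one, so the decisions are ordered:
#' the double correction is an upper bound on violation detection and the
#' single correction a lower bound. When both agree the verdict is certain;
#' when only the double correction flags a violation the verdict is
#' `"uncertain"`.
#'
#' @param dim_x,dim_y [dimension_summary()] objects.
#' @param r_manifest Observed correlation between the two composite scores.
#'
#' @return An object of class `"pair_assessment"`: a list with fields
#'   `pair`, `ave_x`, `ave_y`, `r_manifest`, `r_hat_double`, `r_hat_single`,
#'   `double_met`, `single_met`, `verdict` (one of `"distinct_certain"`,
#'   `"violation_certain"`, `"uncertain"`), and `overcorrected_flag`.
#' @examples
#' a <- dimension_summary("x", 0.742424, 3)
#' assess_pair(a, a, 0.445455)$verdict  # "distinct_certain"
#' @export
assess_pair <- function(dim_x, dim_y, r_manifest) {
  stopifnot(inherits(dim_x, "dimension_summary"),
            inherits(dim_y, "dimension_summary"))
  ave_x <- ave_from_alpha(dim_x$alpha, dim_x$n_items)
  ave_y <- ave_from_alpha(dim_y$alpha, dim_y$n_items)
  r_hat_double <- disattenuate(r_manifest, dim_x$alpha, dim_y$alpha, "double")
  r_hat_single <- disattenuate(r_manifest, dim_x$alpha, dim_y$alpha, "single")
  double_met <- .fl_met(ave_x, r_hat_double^2) &&
                .fl_met(ave_y, r_hat_double^2)
  single_met <- .fl_met(ave_x, r_hat_single^2) &&
                .fl_met(ave_y, r_hat_single^2)
  if (double_met && !single_met) {
    # impossible: |r_hat_single| <= |r_hat_double| always
    stop("internal consistency error: double correction met while single ",
         "correction violated for pair (", dim_x$name, ", ", dim_y$name, ")",
         call. = FALSE)
  }
  verdict <- if (double_met) "distinct_certain"
             else if (!single_met) "violation_certain"
             else "uncertain"
  structure(list(
    pair = c(dim_x$name, dim_y$name),
    ave_x = ave_x, ave_y = ave_y,
    r_manifest = r_manifest,
    r_hat_double = r_hat_double, r_hat_single = r_hat_single,
    double_met = double_met, single_met = single_met,
    verdict = verdict,
    overcorrected_flag = abs(r_hat_double) > 1 || abs(r_hat_single) > 1
  ), class = "pair_assessment")
}

#' @export
print.pair_assessment <- function(x, ...) {
  cat(sprintf("<pair> %s -- %s\n", x$pair[1], x$pair[2]))
  cat(sprintf("  AVE: %.4f / %.4f   r = %.4f\n", x$ave_x, x$ave_y,
              x$r_manifest))
  cat(sprintf("  r-hat double = %.4f (%s)   single = %.4f (%s)%s\n",
              x$r_hat_double, if (x$double_met) "met" else "violated",
              x$r_hat_single, if (x$single_met) "met" else "violated",
              if (x$overcorrected_flag) "   [overcorrected]" else ""))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Assess every dimension pair of an instrument
#'
#' Runs [assess_pair()] on each of the D(D-1)/2 unordered dimension pairs
#' and summarizes the instrument-level outcome. The instrument "meets" the
#' manifest Fornell-Larcker criterion only when every pair is
#' `distinct_certain`; the violation fraction counts pairs with verdict
#' `violation_certain`, and the not-distinct fraction counts all pairs
#' whose verdict is not `distinct_certain`.
#'
#' @param instr An [instrument_summary()].
#'
#' @return An object of class `"instrument_assessment"`: a list with
#'   `pairs` (list of `pair_assessment`) and `summary` (list with `n_pairs`,
#'   `mfl_met`, `n_violation`, `n_uncertain`, `violation_fraction`,
#'   `not_distinct_fraction`).
#' @export
assess_instrument <- function(instr) {
  stopifnot(inherits(instr, "instrument_summary"))
  dims <- instr$dimensions
  d <- length(dims)
  pairs <- list()
  for (i in seq_len(d - 1L)) {
    for (j in seq.int(i + 1L, d)) {
      pairs[[length(pairs) + 1L]] <-
        assess_pair(dims[[i]], dims[[j]], instr$composite_corr[i, j])
    }
  }
  verdicts <- vapply(pairs, `[[`, character(1), "verdict")
  n_pairs <- length(pairs)
  summary <- list(
    n_pairs = n_pairs,
    mfl_met = all(verdicts == "distinct_certain"),
    n_violation = sum(verdicts == "violation_certain"),
    n_uncertain = sum(verdicts == "uncertain"),
    violation_fraction = mean(verdicts == "violation_certain"),
    not_distinct_fraction = mean(verdicts != "distinct_certain")
  )
  structure(list(pairs = pairs, summary = summary),
            class = "instrument_assessment")
}

#' @export
print.instrument_assessment <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<assessment> %d pairs: %d violation, %d uncertain -> mFL %s\n",
              s$n_pairs, s$n_violation, s$n_uncertain,
              if (s$mfl_met) "met" else "NOT met"))
  for (p in x$pairs) print(p)
  invisible(x)
}

#' Tabulate pair assessments
#'
#' @param x An `"instrument_assessment"` or list of `"pair_assessment"`.
#' @return A data.frame with one row per pair.
#' @export
as.data.frame.instrument_assessment <- function(x, ...) {
  do.call(rbind, lapply(x$pairs, function(p) {
    data.frame(dim_x = p$pair[1], dim_y = p$pair[2],
               ave_x = p$ave_x, ave_y = p$ave_y,
               r_manifest = p$r_manifest,
               r_hat_double = p$r_hat_double, r_hat_single = p$r_hat_single,
               double_met = p$double_met, single_met = p$single_met,
               verdict = p$verdict,
               overcorrected = p$overcorrected_flag,
               stringsAsFactors = FALSE)
  }))
}
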