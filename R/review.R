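# Batch assessment of published instrument summaries and the
# systematic-review statistics (contingency test across journals,
# structure-vs-verdict comparisons).

#' Chi-square test of independence for a labeled contingency table
#'
#' Pearson chi-square without continuity correction;
#' `df = (rows - 1) * (cols - 1)`, p-value from the upper tail.
#'
#' @param counts Matrix of non-negative integer counts, at least 2 x 2,
#'   optionally with dimnames.
#' @return A list: `statistic`, `df`, `p_value`, `n` (grand total).
#' @examples
#' # met / not-met by journal
#' chisq_independence(rbind(c(5, 4), c(4, 5), c(8, 15)))
#' @export
chisq_independence <- function(counts) {
  x <- as.matrix(counts)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  }
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(x) < 1) stop("grand total must be >= 1", call. = FALSE)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("degenerate table: a zero row/column marginal makes expected ",
         "counts zero", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), n = sum(x))
}

#' Journal-level counts from the published systematic review
#'
#' The met / not-met by journal table among the instruments with enough
#' information to evaluate the manifest criterion: 5 of 9, 4 of 9 and
#' 8 of 23 instruments met it in the three journals reviewed (N = 41).
#'
#' @return A 3 x 2 integer matrix with journal rows and
#'   `met` / `not_met` columns.
#' @export
review_table_counts <- function() {
  path <- system.file("extdata", "review_counts.csv",
                      package = "manifestFL", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, c("met", "not_met")])
  rownames(m) <- df$journal
  storage.mode(m) <- "integer"
  m
}

#' Assess a batch of instruments
#'
#' Runs [assess_instrument()] on each summary and aggregates the review
#' statistics: how many instruments meet the manifest criterion on every
#' pair, and — among instruments with at least one certain violation — the
#' mean fraction of non-redundant pairs violated.
#'
#' @param instruments List of [instrument_summary()] objects, optionally
#'   named.
#' @return A list of class `"review_batch"`: `records` (data.frame with one
#'   row per instrument: `instrument`, `n_dimensions`,
#'   `n_nonredundant_pairs`, `mean_items_per_dimension`, `mfl_met`,
#'   `n_uncertain`, `violation_fraction`, `error`), `assessments` (list),
#'   and `summary` (list with `n_instruments`, `n_met`, `n_not_met`,
#'   `mean_violation_fraction_when_violated`, `NA` when no instrument has a
#'   violation).
#' @export
review_batch <- function(instruments) {
  if (length(instruments) == 0L) {
    return(structure(list(
      records = data.frame(), assessments = list(),
      summary = list(n_instruments = 0L, n_met = 0L, n_not_met = 0L,
                     mean_violation_fraction_when_violated = NA_real_)),
      class = "review_batch"))
  }
  ids <- names(instruments)
  if (is.null(ids)) ids <- paste0("instrument_", seq_along(instruments))
  rows <- vector("list", length(instruments))
  assessments <- vector("list", length(instruments))
  for (i in seq_along(instruments)) {
    res <- tryCatch(assess_instrument(instruments[[i]]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(
        instrument = ids[i], n_dimensions = NA_integer_,
        n_nonredundant_pairs = NA_integer_,
        mean_items_per_dimension = NA_real_, mfl_met = NA,
        n_uncertain = NA_integer_, violation_fraction = NA_real_,
        error = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    assessments[[i]] <- res
    dims <- instruments[[i]]$dimensions
    rows[[i]] <- data.frame(
      instrument = ids[i],
      n_dimensions = length(dims),
      n_nonredundant_pairs = res$summary$n_pairs,
      mean_items_per_dimension =
        mean(vapply(dims, `[[`, integer(1), "n_items")),
      mfl_met = res$summary$mfl_met,
      n_uncertain = res$summary$n_uncertain,
      violation_fraction = res$summary$violation_fraction,
      error = NA_character_, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  names(assessments) <- ids
  ok <- !is.na(records$mfl_met)
  violated <- ok & records$violation_fraction > 0
  structure(list(
    records = records, assessments = assessments,
    summary = list(
      n_instruments = length(instruments),
      n_met = sum(records$mfl_met[ok]),
      n_not_met = sum(!records$mfl_met[ok]),
      mean_violation_fraction_when_violated =
        if (any(violated)) mean(records$violation_fraction[violated])
        else NA_real_)),
    class = "review_batch")
}

#' @export
print.review_batch <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<review_batch> %d instruments: %d met, %d not met\n",
              s$n_instruments, s$n_met, s$n_not_met))
  if (!is.na(s$mean_violation_fraction_when_violated)) {
    cat(sprintf("  mean violation fraction (violated instruments): %.1f%%\n",
                100 * s$mean_violation_fraction_when_violated))
  }
  invisible(x)
}

#' Compare an instrument-structure feature between verdict groups
#'
#' Two-sample Student (pooled-variance) t test of a structural feature
#' (number of non-redundant pairs, or mean items per dimension) between
#' instruments that meet the manifest criterion and those that do not,
#' with `df = n1 + n2 - 2`.
#'
#' @param records Data.frame as returned in `review_batch()$records`
#'   (needs columns `mfl_met` and the feature).
#' @param feature `"n_nonredundant_pairs"` or `"mean_items_per_dimension"`.
#' @return A list: `t_statistic`, `df`, `p_value`, group means.
#' @export
compare_structure_by_verdict <- function(records,
                                         feature = c(
                                           "n_nonredundant_pairs",
                                           "mean_items_per_dimension")) {
  feature <- match.arg(feature)
  ok <- !is.na(records$mfl_met) & !is.na(records[[feature]])
  g_met <- records[[feature]][ok & records$mfl_met]
  g_not <- records[[feature]][ok & !records$mfl_met]
  if (length(g_met) < 2L || length(g_not) < 2L) {
    stop("both verdict groups need >= 2 instruments for the pooled t test",
         call. = FALSE)
  }
  tt <- stats::t.test(g_met, g_not, var.equal = TRUE)
  list(t_statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = unname(tt$p.value),
       mean_met = mean(g_met), mean_not_met = mean(g_not))
}
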