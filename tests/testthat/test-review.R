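test_that("chi-square of independence matches a first-principles oracle", {
  tab <- rbind(c(5, 4), c(4, 5), c(8, 15))
  ct <- chisq_independence(tab)
  expect_equal(ct$statistic, chisq_oracle(tab), tolerance = 1e-12)
  expect_equal(ct$df, 2)
  expect_equal(ct$n, 41)

  # proportional rows: exact independence
  expect_equal(chisq_independence(rbind(c(2, 4), c(3, 6)))$statistic, 0)
  # 2x2 identity with N = 2: all expected 0.5
  expect_equal(chisq_independence(rbind(c(1, 0), c(0, 1)))$statistic, 2)
})

test_that("chi-square is invariant to permutation and transposition", {
  tab <- rbind(c(5, 4), c(4, 5), c(8, 15))
  base <- chisq_independence(tab)$statistic
  expect_equal(chisq_independence(tab[c(3, 1, 2), ])$statistic, base)
  expect_equal(chisq_independence(tab[, c(2, 1)])$statistic, base)
  expect_equal(chisq_independence(t(tab))$statistic, base)
})

test_that("degenerate tables are rejected", {
  expect_error(chisq_independence(rbind(c(0, 0), c(3, 4))), "marginal")
  expect_error(chisq_independence(matrix(1, 1, 2)), "2 x 2")
  expect_error(chisq_independence(rbind(c(1.5, 2), c(3, 4))), "integers")
})

test_that("bundled review counts reproduce the published contingency test", {
  counts <- review_table_counts()
  expect_equal(unname(rowSums(counts)), c(9, 9, 23))
  ct <- chisq_independence(counts)
  expect_equal(round(ct$statistic, 2), 1.19)
  expect_equal(ct$df, 2)
  expect_equal(ct$n, 41)
  expect_equal(round(ct$p_value, 2), 0.55)
})

test_that("pooled t comparison matches the hand formula", {
  rec <- data.frame(
    mfl_met = rep(c(TRUE, FALSE), each = 3),
    n_nonredundant_pairs = c(1, 2, 3, 4, 5, 6),
    mean_items_per_dimension = rep(5, 6))
  ct <- compare_structure_by_verdict(rec, "n_nonredundant_pairs")
  expect_equal(ct$t_statistic, pooled_t_oracle(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
  expect_equal(round(ct$t_statistic, 4), -3.6742)
  expect_equal(ct$df, 4)
  # identical feature values in both groups: t = 0
  rec2 <- rec
  rec2$n_nonredundant_pairs <- c(1, 2, 3, 1, 2, 3)
  expect_equal(compare_structure_by_verdict(
    rec2, "n_nonredundant_pairs")$t_statistic, 0)
  # df arithmetic for group sizes 17 and 24
  rec3 <- data.frame(mfl_met = rep(c(TRUE, FALSE), c(17, 24)),
                     n_nonredundant_pairs = rnorm(41),
                     mean_items_per_dimension = rnorm(41))
  expect_equal(compare_structure_by_verdict(rec3,
                                            "n_nonredundant_pairs")$df, 39)
  expect_error(compare_structure_by_verdict(
    data.frame(mfl_met = TRUE, n_nonredundant_pairs = 1,
               mean_items_per_dimension = 1), "n_nonredundant_pairs"),
    "verdict groups")
})

test_that("review batches aggregate instrument verdicts", {
  # three tau-equivalent instruments at population phi = 0.2: all distinct
  a <- tau_alpha()
  mk_pop <- function(phi) {
    instrument_summary(
      list(dimension_summary("x", a, 3), dimension_summary("y", a, 3)),
      matrix(c(1, tau_r_pop(phi), tau_r_pop(phi), 1), 2, 2))
  }
  rb <- review_batch(list(i1 = mk_pop(0.2), i2 = mk_pop(0.15),
                          i3 = mk_pop(0.25)))
  expect_equal(rb$summary$n_met, 3)
  expect_equal(rb$summary$n_not_met, 0)
  expect_true(is.na(rb$summary$mean_violation_fraction_when_violated))

  # one instrument whose every pair is certainly violated
  bad <- instrument_summary(
    lapply(1:3, function(i) dimension_summary(paste0("d", i), 0.8, 4)),
    const_corr(3, 0.95))
  rb2 <- review_batch(list(good = mk_pop(0.2), bad = bad))
  expect_equal(rb2$records$violation_fraction[
    rb2$records$instrument == "bad"], 1)
  expect_equal(rb2$summary$mean_violation_fraction_when_violated, 1)

  # empty batch: empty output, no error
  rb0 <- review_batch(list())
  expect_equal(rb0$summary$n_instruments, 0)
  expect_equal(nrow(rb0$records), 0)
})

test_that("review batches are order-invariant over records", {
  a <- tau_alpha()
  ins <- list(
    one = instrument_summary(
      list(dimension_summary("x", a, 3), dimension_summary("y", a, 3)),
      const_corr(2, 0.2)),
    two = instrument_summary(
      list(dimension_summary("x", 0.9, 5), dimension_summary("y", 0.7, 4)),
      const_corr(2, 0.85)))
  r12 <- review_batch(ins)$records
  r21 <- review_batch(rev(ins))$records
  expect_equal(r12[order(r12$instrument), ], r21[order(r21$instrument), ],
               ignore_attr = TRUE)
})
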