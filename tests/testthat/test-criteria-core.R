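test_that("standardized alpha matches the closed form on constant matrices", {
  # K = 3, rbar = 0.49: 3 * 0.49 / (1 + 2 * 0.49) = 1.47 / 1.98
  expect_equal(standardized_alpha(const_corr(3, 0.49)), 1.47 / 1.98,
               tolerance = 1e-12)
  expect_equal(standardized_alpha(diag(4)), 0)
  expect_equal(standardized_alpha(const_corr(2, 1.0)), 1.0)
})

test_that("standardized alpha rejects malformed and degenerate input", {
  expect_error(standardized_alpha(matrix(1, 1, 1)), "K >= 2")
  expect_error(standardized_alpha(matrix(0.5, 2, 3)), "square")
  m <- const_corr(3, 0.2); m[1, 2] <- 0.9  # asymmetric
  expect_error(standardized_alpha(m), "symmetric")
  # rbar = -0.5 = -1/(K-1) for K = 3: zero denominator
  expect_error(standardized_alpha(const_corr(3, -0.5)), "undefined")
})

test_that("AVE from loadings is the mean squared loading", {
  expect_equal(ave_from_loadings(c(0.7, 0.7, 0.7)), 0.49)
  expect_equal(ave_from_loadings(c(0.45, 0.70, 0.95)),
               (0.2025 + 0.49 + 0.9025) / 3)
  expect_equal(ave_from_loadings(c(1, 1)), 1)
  expect_error(ave_from_loadings(0.7), "length >= 2")
  expect_error(ave_from_loadings(c(0.7, 1.2)), "\\(-1, 1\\]")
})

test_that("AVE from alpha inverts the standardized-alpha formula", {
  expect_equal(ave_from_alpha(standardized_alpha(const_corr(3, 0.49)), 3),
               0.49, tolerance = 1e-12)
  for (k in c(2, 5, 9)) expect_equal(ave_from_alpha(1, k), 1)
  expect_equal(ave_from_alpha(0.9, 4), 0.9 / 1.3, tolerance = 1e-12)
  expect_equal(ave_from_alpha(0.6, 4), 0.6 / 2.2, tolerance = 1e-12)
  expect_error(ave_from_alpha(0, 3), "\\(0, 1\\]")
  expect_error(ave_from_alpha(1.2, 3), "\\(0, 1\\]")
})

test_that("alpha <-> AVE round-trip holds across random (K, rbar) draws", {
  set.seed(11)
  for (i in 1:200) {
    k <- sample(2:12, 1)
    rbar <- runif(1, 0.05, 0.95)
    expect_equal(ave_from_alpha(standardized_alpha(const_corr(k, rbar)), k),
                 rbar, tolerance = 1e-12)
  }
})

test_that("disattenuation divides by the right reliability term", {
  a <- tau_alpha()
  # double correction recovers phi from the population composite correlation
  expect_equal(disattenuate(tau_r_pop(0.6), a, a, "double"), 0.6,
               tolerance = 1e-12)
  expect_equal(disattenuate(0.5, 1, 1, "double"), 0.5)
  expect_equal(disattenuate(0.5, 1, 1, "single"), 0.5)
  expect_equal(disattenuate(0.5, 0.9, 0.6, "single"), 0.5 / sqrt(0.6))
  expect_equal(disattenuate(0.5, 0.9, 0.6, "double"), 0.5 / sqrt(0.54))
  # overcorrection is returned raw, not clamped
  expect_gt(disattenuate(0.9, 0.5, 0.5, "double"), 1)
  expect_error(disattenuate(0.5, 0, 0.8, "double"), "reliabilit")
})

test_that("original criterion compares both AVEs to the squared correlation", {
  expect_true(ofl_pair(0.49, 0.49, 0.60))
  expect_false(ofl_pair(0.49, 0.49, 0.72))
  expect_true(ofl_pair(0.2, 0.3, 0))
  # one-sided failure is a violation
  expect_false(ofl_pair(0.3, 0.9, 0.6))
  # sign-symmetric in phi
  expect_identical(ofl_pair(0.49, 0.49, -0.72), ofl_pair(0.49, 0.49, 0.72))
})

test_that("manifest criterion reproduces the tau-equivalent identity", {
  a <- tau_alpha()
  d <- dimension_summary("x", a, 3)
  # equals ofl_pair(0.49, 0.49, phi) for the tau-equivalent population
  for (phi in c(0.2, 0.6, 0.69, 0.72, 0.9)) {
    expect_identical(mfl_pair(d, d, tau_r_pop(phi), "double"),
                     ofl_pair(0.49, 0.49, phi), label = paste("phi", phi))
  }
  expect_true(mfl_pair(d, d, 0, "double"))
  expect_true(mfl_pair(d, d, 0, "single"))
  # single correction: AVE_y = 0.6/2.2 < 0.5^2/0.6
  expect_false(mfl_pair(dimension_summary("x", 0.9, 4),
                        dimension_summary("y", 0.6, 4), 0.5, "single"))
})

test_that("pair assessment fills fields and assigns the right verdict", {
  a <- tau_alpha()
  dx <- dimension_summary("x", a, 3)
  pa <- assess_pair(dx, dx, tau_r_pop(0.6))
  expect_s3_class(pa, "pair_assessment")
  expect_equal(pa$ave_x, 0.49, tolerance = 1e-12)
  expect_equal(pa$r_hat_double, 0.6, tolerance = 1e-12)
  expect_identical(pa$verdict, "distinct_certain")
  expect_false(pa$overcorrected_flag)

  pv <- assess_pair(dimension_summary("x", 0.9, 4),
                    dimension_summary("y", 0.6, 4), 0.5)
  expect_identical(pv$verdict, "violation_certain")

  # straddling the bound: double violated, single met
  pu <- assess_pair(dx, dx, 0.52)
  expect_false(pu$double_met)
  expect_true(pu$single_met)
  expect_identical(pu$verdict, "uncertain")
})

test_that("single correction never flags what double correction misses", {
  set.seed(23)
  for (i in 1:300) {
    ax <- runif(1, 0.3, 1); ay <- runif(1, 0.3, 1)
    kx <- sample(2:10, 1); ky <- sample(2:10, 1)
    r <- runif(1, -0.95, 0.95)
    dx <- dimension_summary("x", ax, kx)
    dy <- dimension_summary("y", ay, ky)
    expect_lte(abs(disattenuate(r, ax, ay, "single")),
               abs(disattenuate(r, ax, ay, "double")) + 1e-12)
    expect_true(mfl_pair(dx, dy, r, "single") >= mfl_pair(dx, dy, r, "double"))
    # assess_pair must never hit its internal-consistency stop
    expect_no_error(assess_pair(dx, dy, r))
  }
})

test_that("raising |r| can only switch a pair from met to violated", {
  dx <- dimension_summary("x", 0.8, 5)
  dy <- dimension_summary("y", 0.75, 4)
  for (mode in c("double", "single")) {
    dec <- vapply(seq(0, 0.95, by = 0.05),
                  function(r) mfl_pair(dx, dy, r, mode), logical(1))
    expect_true(all(diff(dec) <= 0), label = mode)  # non-increasing
  }
})

test_that("instrument assessment enumerates unordered pairs", {
  mk <- function(d, r) {
    dims <- lapply(seq_len(d), function(i)
      dimension_summary(paste0("d", i), 0.8, 4))
    instrument_summary(dims, const_corr(d, r))
  }
  expect_length(assess_instrument(mk(2, 0.3))$pairs, 1L)
  expect_length(assess_instrument(mk(5, 0.3))$pairs, 10L)
  a0 <- assess_instrument(mk(4, 0))
  expect_true(a0$summary$mfl_met)
  expect_equal(a0$summary$violation_fraction, 0)
  # highly correlated composites: every pair certainly violated
  a1 <- assess_instrument(mk(3, 0.95))
  expect_false(a1$summary$mfl_met)
  expect_equal(a1$summary$violation_fraction, 1)
})

test_that("constructors validate their invariants", {
  expect_error(dimension_summary("x", 1.2, 3), "alpha")
  expect_error(dimension_summary("x", 0.8, 1), "n_items")
  d <- dimension_summary("x", 0.8, 3)
  expect_error(instrument_summary(list(d), matrix(1)), ">= 2")
  m <- const_corr(2, 0.4); m[1, 2] <- 0.42  # asymmetric beyond 1e-6
  expect_error(
    instrument_summary(list(d, dimension_summary("y", 0.7, 4)), m),
    "asymmetric")
  md <- const_corr(2, 0.4); diag(md) <- c(1, 0.9)
  expect_error(
    instrument_summary(list(d, dimension_summary("y", 0.7, 4)), md),
    "diagonal")
})
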