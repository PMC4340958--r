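test_that("double-positive gating keeps events above both thresholds", {
  ev <- tibble::tibble(egfp = c(1, 50, 50, 200), mcherry = c(50, 1, 50, 200))
  g <- gate_double_positive(ev, 10, 10)
  expect_equal(nrow(g), 2)
  expect_true(all(g$egfp > 10 & g$mcherry > 10))
  # thresholds at 0+ retain everything
  expect_equal(nrow(gate_double_positive(ev, 1e-9, 1e-9)), 4)
  expect_error(gate_double_positive(ev, 1000, 1000), "empty gate")
  expect_error(gate_double_positive(ev, -1, 10), "positive")
})

test_that("gating removes the untransduced floor", {
  ev <- generate_dual_reporter(2e4, 0.5, residual_cv = 20,
                               untransduced_fraction = 0.3, seed = 1)
  g <- gate_double_positive(ev, 20, 20)
  # every floor event falls, along with dim transduced cells
  expect_equal(sum(!g$transduced), 0)
  kept <- nrow(g) / nrow(ev)
  expect_lt(kept, 0.7)
  expect_gt(kept, 0.4)
})

test_that("orthogonal fit matches the closed-form TLS slope", {
  ev <- generate_dual_reporter(3000, 0.7, residual_cv = 25,
                               untransduced_fraction = 0, seed = 2)
  f <- orthogonal_fit(ev$egfp, ev$mcherry)
  expect_equal(f$slope, tls_slope_closed_form(ev$mcherry, ev$egfp),
               tolerance = 1e-10)
  expect_equal(f$n, 3000)
  expect_equal(f$space, "linear")
})

test_that("identical channels fit slope 1; swapping channels inverts the slope", {
  x <- rlnorm(500, 5, 1)
  expect_equal(orthogonal_fit(x, x)$slope, 1)
  ev <- generate_dual_reporter(4000, 0.5, residual_cv = 20,
                               untransduced_fraction = 0, seed = 3)
  f <- orthogonal_fit(ev$egfp, ev$mcherry)
  swapped <- orthogonal_fit(ev$mcherry, ev$egfp)
  expect_equal(swapped$slope, 1 / f$slope, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected", {
  expect_error(orthogonal_fit(1:5, 1:5), "at least 10")
  expect_error(orthogonal_fit(rep(1, 20), rlnorm(20, 3, 1)), "zero variance")
})

test_that("the fitted slope is centred on the generator truth across the grid", {
  # TLS under a single-axis multiplicative residual has an O(s^2 cv^2)
  # upward bias and heavy-tailed sampling noise (see the vignette), so the
  # estimator's central accuracy is measured over replicate datasets
  for (s in c(0.25, 0.5, 1, 2)) {
    for (rcv in c(10, 30)) {
      errs <- vapply(1:20, function(k) {
        ev <- generate_dual_reporter(5000, s, residual_cv = rcv,
                                     untransduced_fraction = 0,
                                     seed = 1000 * k + s * 100 + rcv)
        orthogonal_fit(ev$egfp, ev$mcherry)$slope / s - 1
      }, numeric(1))
      expect_lt(abs(mean(errs)), 0.10)
    }
  }
})

test_that("log-space fitting recovers the log-log relationship", {
  # proportional channels: exactly unit slope, intercept = log10(ratio)
  ev0 <- generate_dual_reporter(1000, 0.5, residual_cv = 0,
                                untransduced_fraction = 0, seed = 4)
  f0 <- orthogonal_fit(ev0$egfp, ev0$mcherry, log_space = TRUE)
  expect_equal(f0$space, "log10")
  expect_equal(f0$slope, 1, tolerance = 1e-10)
  expect_equal(10^f0$intercept, 0.5, tolerance = 1e-10)
  # with a multiplicative residual the log-log slope stays near 1
  ev <- generate_dual_reporter(5000, 0.5, residual_cv = 30,
                               untransduced_fraction = 0, seed = 4)
  f <- orthogonal_fit(ev$egfp, ev$mcherry, log_space = TRUE)
  expect_equal(f$slope, 1, tolerance = 0.05)
})

test_that("empty-vector normalisation is exact and scale-invariant", {
  ev <- generate_dual_reporter(2000, 0.8, residual_cv = 20,
                               untransduced_fraction = 0, seed = 5)
  f <- orthogonal_fit(ev$egfp, ev$mcherry)
  self <- normalize_to_empty(f, f)
  expect_equal(self$relative_expression, 1)
  # rescaling both channels by a common factor leaves the ratio unchanged
  f2 <- orthogonal_fit(ev$egfp * 3.5, ev$mcherry * 3.5)
  expect_equal(normalize_to_empty(f2, f2)$relative_expression, 1)
  expect_equal(f2$slope, f$slope, tolerance = 1e-10)
})

test_that("the reporter pipeline recovers a 2-fold repression", {
  mk_fit <- function(slope, seed) {
    ev <- generate_dual_reporter(5000, slope, residual_cv = 20,
                                 untransduced_fraction = 0.3, seed = seed)
    orthogonal_fit(gate_double_positive(ev, 20, 20)$egfp,
                   gate_double_positive(ev, 20, 20)$mcherry)
  }
  f_empty <- mk_fit(0.8, 11)
  f_utr <- mk_fit(0.4, 12)       # 2-fold repressed in control cells
  f_utr_dicer <- mk_fit(0.8, 13) # repression lost without microRNAs
  norm_ctrl <- normalize_to_empty(f_utr, f_empty, "cd69_utr", "control")
  norm_dicer <- normalize_to_empty(f_utr_dicer, f_empty, "cd69_utr",
                                   "deficient")
  expect_equal(norm_ctrl$relative_expression, 0.5, tolerance = 0.07)
  expect_equal(derepression_ratio(norm_ctrl, norm_dicer), 2,
               tolerance = 0.15)
  # direct-ratio sanity values
  expect_equal(derepression_ratio(0.5, 0.75), 1.5)
  expect_equal(derepression_ratio(1, 1), 1)
  expect_error(derepression_ratio(0, 1), "positive")
})
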