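test_that("cv computes the sample coefficient of variation in percent", {
  expect_equal(cv(c(90, 100, 110)), 10)
  expect_equal(cv(rep(5, 10)), 0)
  x <- rlnorm(100, 4, 0.3)
  expect_equal(cv(3.7 * x), cv(x))  # scale invariance
  expect_error(cv(5), "at least 2")
  expect_error(cv(c(-10, 2)), "positive")
  s <- cv_summary(c(90, 100, 110))
  expect_equal(s$mean, 100)
  expect_equal(s$sd, 10)
  expect_equal(s$n, 3)
})

test_that("ratio CV bounds technical noise and cancels biology", {
  # perfectly proportional channels carry no ratio noise
  x <- rlnorm(500, 3, 0.5)
  expect_equal(technical_noise_bound(2 * x, x)$cv, 0)
  # technical CV 5% per channel: ratio CV = sqrt((1+0.05^2)^2 - 1) ~ 7.1%
  ev <- generate_paired_channels(5e4, 100, 80, 30, 5, seed = 1)
  expect_equal(technical_noise_bound(ev$a, ev$b)$cv,
               100 * sqrt((1 + 0.05^2)^2 - 1), tolerance = 0.05)
  # breaking the pairing exposes the biological variation
  shuffled <- technical_noise_bound(ev$a, sample(ev$b))$cv
  expect_gt(shuffled, 4 * technical_noise_bound(ev$a, ev$b)$cv)
  expect_error(technical_noise_bound(1:5, 1:4), "equal lengths")
})

test_that("the ratio CV is invariant to the shared biological CV", {
  cvs <- vapply(c(10, 30, 50), function(bio) {
    ev <- generate_paired_channels(5e4, 100, 80, bio, 5, seed = 2)
    technical_noise_bound(ev$a, ev$b)$cv
  }, numeric(1))
  expect_lt(max(cvs) - min(cvs), 0.5)
})

test_that("peak-channel skew reflects distribution asymmetry", {
  # symmetric on the log scale: tails balance within sampling error
  set.seed(3)
  sym <- 10^rnorm(5e4, 2, 0.2)
  ps <- peak_channel_skew(sym, n_bins = 128)
  expect_lt(abs(ps$fraction_below - ps$fraction_above), 0.06)
  # low-mean minority component drags mass below the peak
  mix <- generate_mixture(
    list(list(fraction = 0.2, spec = population_spec(100, 20)),
         list(fraction = 0.8, spec = population_spec(200, 20))),
    5e4, seed = 4)
  pm <- peak_channel_skew(mix$intensity, n_bins = 128)
  expect_gt(pm$fraction_below, pm$fraction_above)
  # broad single log-normal viewed on log bins is near-symmetric, so build
  # a right-skewed profile as a high-mean minority shoulder
  right <- generate_mixture(
    list(list(fraction = 0.8, spec = population_spec(100, 20)),
         list(fraction = 0.2, spec = population_spec(250, 30))),
    5e4, seed = 5)
  pr <- peak_channel_skew(right$intensity, n_bins = 128)
  expect_gt(pr$fraction_above, pr$fraction_below)
  expect_error(peak_channel_skew(numeric(0)), "empty")
  expect_error(peak_channel_skew(rlnorm(50)), "at least 100")
})

test_that("analytic mixture CV follows the law of total variance", {
  expect_equal(mixture_cv_analytic(data.frame(fraction = 1, mean = 100,
                                              cv = 20)), 20)
  # hand computation: Var = .2*(.2*1)^2+.8*(.2*2)^2+.2*(1-1.8)^2+.8*(2-1.8)^2
  hand <- 100 * sqrt(0.296) / 1.8
  expect_equal(mixture_cv_analytic(data.frame(fraction = c(0.2, 0.8),
                                              mean = c(1, 2), cv = 20)),
               hand)
  expect_equal(hand, 30.22, tolerance = 0.01)
  # equal-CV components with different means always inflate the CV
  expect_gt(mixture_cv_analytic(data.frame(fraction = c(0.5, 0.5),
                                           mean = c(1, 3), cv = 15)), 15)
  expect_error(mixture_cv_analytic(data.frame(fraction = c(0.3, 0.3),
                                              mean = c(1, 2), cv = 20)),
               "sum to 1")
})

test_that("analytic and empirical mixture CVs agree", {
  n <- 1e5
  comps <- list(list(fraction = 0.2, spec = population_spec(100, 20)),
                list(fraction = 0.8, spec = population_spec(200, 20)))
  mix <- generate_mixture(comps, n, seed = 6)
  analytic <- mixture_cv_analytic(data.frame(fraction = c(0.2, 0.8),
                                             mean = c(100, 200), cv = 20))
  empirical <- cv(mix$intensity)
  # block SE of the empirical CV
  blocks <- split(mix$intensity, rep(1:20, length.out = n))
  se <- sd(vapply(blocks, cv, numeric(1))) / sqrt(20)
  expect_lt(abs(empirical - analytic), 3 * se)
})

test_that("unmixing reproduces the sample CV at zero removal", {
  mix <- generate_mixture(
    list(list(fraction = 0.1, spec = population_spec(100, 25)),
         list(fraction = 0.9, spec = population_spec(300, 25))),
    2e4, seed = 7)
  ref <- generate_population(population_spec(100, 25), seed = 8, n = 2e4)
  curve <- unmix_cv_curve(mix$intensity, ref$intensity,
                          fraction_grid = seq(0, 0.2, by = 0.02))
  expect_equal(curve$cv_remainder[1], cv(mix$intensity))
  expect_equal(curve$mass_remaining[1], 1)
})

test_that("removing a low-mean contaminant lowers the CV back to the majority", {
  n <- 5e4
  mix <- generate_mixture(
    list(list(fraction = 0.1, spec = population_spec(100, 25)),
         list(fraction = 0.9, spec = population_spec(300, 25))),
    n, seed = 9)
  ref <- generate_population(population_spec(100, 25), seed = 10, n = n)
  curve <- unmix_cv_curve(mix$intensity, ref$intensity,
                          fraction_grid = seq(0, 0.12, by = 0.01))
  expect_true(all(diff(curve$cv_remainder) <= 1e-9))
  # full removal of the 10% contaminant recovers the pure-majority CV
  cv_full <- curve$cv_remainder[curve$fraction == 0.1]
  expect_lt(abs(cv_full - 25), 1)
  # interpolated fraction for a 1-point CV drop is well inside the grid
  f1 <- unmix_fraction_for_reduction(curve, 1)
  expect_true(f1 > 0 && f1 < 0.1)
})

test_that("removal proportional to the mixture itself leaves the CV unchanged", {
  x <- generate_population(population_spec(200, 30), seed = 11, n = 2e4)
  curve <- unmix_cv_curve(x$intensity, x$intensity,
                          fraction_grid = c(0, 0.1, 0.3, 0.5))
  expect_equal(curve$cv_remainder, rep(cv(x$intensity), 4),
               tolerance = 1e-10)
})

test_that("unmixing warns and truncates when the remainder vanishes", {
  set.seed(13)
  x <- rlnorm(500, 5, 0.2)
  expect_warning(
    curve <- unmix_cv_curve(x, x, fraction_grid = c(0, 0.5, 0.999)),
    "truncated")
  expect_equal(nrow(curve), 2)
})

test_that("replicate CV groups are compared with a Welch t-test", {
  a <- c(15.2, 14.8, 15.5, 15.1)
  cmp0 <- compare_cv(a, a)
  expect_equal(cmp0$difference, 0)
  expect_equal(cmp0$p_value, 1)
  set.seed(12)
  g1 <- rnorm(8, 15, 1)
  g2 <- rnorm(8, 20, 1)
  cmp <- compare_cv(g1, g2)
  expect_lt(cmp$p_value, 0.001)
  expect_lt(cmp$difference, 0)
  swapped <- compare_cv(g2, g1)
  expect_equal(swapped$difference, -cmp$difference)
  expect_equal(swapped$p_value, cmp$p_value)
  # data-frame input uses the cv column
  expect_equal(compare_cv(data.frame(cv = g1), data.frame(cv = g2))$p_value,
               cmp$p_value)
  expect_error(compare_cv(1, c(2, 3)), "2 replicates")
})
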