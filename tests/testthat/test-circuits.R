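test_that("translational circuit has the expected species and reactions", {
  net <- build_translational_ffl(translational_ffl_params())
  expect_equal(species_names(net),
               c("tf_mrna", "tf", "mirna", "mrna", "protein"))
  expect_length(net$reactions, 10)
  # calibrated form adds the constitutive microRNA leak
  net2 <- build_translational_ffl(translational_ffl_params(k_tx_mir_leak = 0.054))
  expect_length(net2$reactions, 11)
})

test_that("degradation circuit adds the microRNA:mRNA complex machinery", {
  net <- build_degradation_ffl(degradation_ffl_params())
  expect_equal(species_names(net),
               c("tf_mrna", "tf", "mirna", "mrna", "complex", "protein"))
  expect_length(net$reactions, 13)
  # translation is unrepressed in this variant
  tl <- net$reactions[[which(vapply(net$reactions, `[[`, character(1),
                                    "name") == "translation")]]
  expect_length(tl$hill, 0)
})

test_that("microRNA molecules are conserved by the complex reactions", {
  net <- build_degradation_ffl(degradation_ffl_params())
  cm <- mirffl:::compile_network(net)
  total_mir <- cm$stoich[, "mirna"] + cm$stoich[, "complex"]
  rx_names <- vapply(net$reactions, `[[`, character(1), "name")
  changes <- rx_names[total_mir != 0]
  expect_setequal(changes, c("mir_transcription", "mir_decay"))
})

test_that("mean-field fixed points match rate-balance algebra", {
  p <- translational_ffl_params()
  ss <- meanfield_steady_state(build_translational_ffl(p))
  expect_equal(unname(ss["tf_mrna"]), 0.06 / 0.006, tolerance = 1e-6)
  expect_equal(unname(ss["tf"]), 10 * 0.04 / 0.002, tolerance = 1e-6)
  H <- hill_activation(200, 200, 2)
  expect_equal(unname(ss["mirna"]), 0.5 * H / 0.006, tolerance = 1e-6)
  expect_equal(unname(ss["mrna"]), 0.8 * H / 0.006, tolerance = 1e-6)
  expect_equal(unname(ss["protein"]),
               unname(ss["mrna"]) * 0.04 *
                 hill_repression(unname(ss["mirna"]), 60, 2) / 0.002,
               tolerance = 1e-5)
})

test_that("disabling the microRNA arm reduces to the unregulated target", {
  p <- translational_ffl_params(k_tx_mir_base = 0)
  ss <- meanfield_steady_state(build_translational_ffl(p))
  expect_equal(unname(ss["mirna"]), 0, tolerance = 1e-8)
  # with no microRNA, repression factor is 1: protein = mrna * k_tl / k_deg
  expect_equal(unname(ss["protein"]),
               unname(ss["mrna"]) * 0.04 / 0.002, tolerance = 1e-5)
  pd <- degradation_ffl_params(k_complex_on = 0)
  ssd <- meanfield_steady_state(build_degradation_ffl(pd))
  expect_equal(unname(ssd["protein"]), unname(ss["protein"]),
               tolerance = 1e-5)
})

test_that("CD69 calibration reproduces the rate-balance constants", {
  p <- calibrate_cd69_model()
  expect_equal(p$k_tx_target, 6 * 0.006 / 0.5)     # 0.072
  expect_equal(p$k_tx_mir_leak, 9 * 0.006)         # 0.054
  expect_equal(p$k_tx_mir_base, (42 - 9) * 0.006 / 0.5)  # 0.396
})

test_that("calibration round-trip recovers copy-number targets within 5%", {
  p <- calibrate_cd69_model()
  ss_act <- meanfield_steady_state(build_translational_ffl(p))
  expect_equal(unname(ss_act["mrna"]), 6, tolerance = 0.05)
  expect_equal(unname(ss_act["mirna"]), 42, tolerance = 0.05)
  p_rest <- p
  p_rest$k_tx_tf <- 0
  ss_rest <- meanfield_steady_state(build_translational_ffl(p_rest))
  expect_equal(unname(ss_rest["mirna"]), 9, tolerance = 0.05)
  expect_equal(unname(ss_rest["mrna"]), 0, tolerance = 1e-6)
})

test_that("infeasible copy-number targets are rejected", {
  expect_error(cd69_model_spec(mrna_resting = 10, mrna_activated = 6),
               "exceed")
  expect_error(cd69_model_spec(mir_resting_central = 50,
                               mir_activated_central = 42), "exceed")
})

test_that("no target transcription means no protein in any scenario", {
  spec <- cd69_model_spec(mrna_activated = 0, mrna_resting = 0)
  p <- calibrate_cd69_model(spec)
  r <- suppressWarnings(run_scenario(p, "activated_with_ffl", n_runs = 50,
                                     t_end = 500, base_seed = 1))
  expect_equal(r$protein_mean, 0)
})

test_that("resting scenario produces essentially no protein", {
  p <- calibrate_cd69_model()
  r <- run_scenario(p, "resting", n_runs = 100, t_end = 1000, base_seed = 4)
  expect_equal(r$protein_mean, 0)
  # resting microRNA pool is sustained by the leak at ~9 copies
  expect_equal(mean(r$ensemble$mirna), 9, tolerance = 0.15)
})

test_that("scenario histograms integrate to the number of runs", {
  p <- calibrate_cd69_model()
  r <- run_scenario(p, "activated_with_ffl", n_runs = 150, t_end = 800,
                    base_seed = 6)
  expect_equal(sum(r$histogram$count), 150)
  expect_equal(r$protein_cv, 100 * r$protein_sd / r$protein_mean)
})

test_that("with- and without-FFL scenarios coincide when the arm has zero rate", {
  p <- translational_ffl_params(k_tx_mir_base = 0, k_tx_mir_leak = 0)
  a <- run_scenario(p, "activated_with_ffl", n_runs = 400, t_end = 1000,
                    base_seed = 21)
  b <- run_scenario(p, "activated_without_ffl", n_runs = 400, t_end = 1000,
                    base_seed = 22)
  expect_gt(two_sample_count_test(a$protein, b$protein), 0.01)
})

test_that("stochastic ensemble means track the mean-field fixed points", {
  p <- translational_ffl_params()
  net <- build_translational_ffl(p)
  ss <- meanfield_steady_state(net)
  ens <- simulate_endpoint_ensemble(net, t_end = 5000, n_runs = 400,
                                    base_seed = 77)
  td <- tidy(ens)
  for (sp in c("tf", "mirna", "mrna", "protein")) {
    expect_lt(abs(td$mean[td$species == sp] / ss[[sp]] - 1), 0.10)
  }
})

test_that("comparing an ensemble with itself gives null differences", {
  p <- calibrate_cd69_model()
  r <- run_scenario(p, "activated_with_ffl", n_runs = 200, t_end = 500,
                    base_seed = 31)
  cmp <- compare_ffl_effect(r, r, n_boot = 200, seed = 1)
  expect_equal(cmp$delta_mean, 0)
  expect_equal(cmp$delta_cv, 0)
  expect_gt(cmp$p_cv, 0.5)
})

test_that("mismatched circuit variants cannot be compared", {
  p <- calibrate_cd69_model()
  pd <- degradation_ffl_params()
  a <- run_scenario(p, "activated_with_ffl", n_runs = 100, t_end = 300,
                    base_seed = 1)
  b <- run_scenario(pd, "activated_with_ffl", n_runs = 100, t_end = 300,
                    base_seed = 1)
  expect_error(compare_ffl_effect(a, b), "variant")
})
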