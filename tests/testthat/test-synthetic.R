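# Two-pool exchange simulator and the Birch-effect experiment generator.

test_that("two-pool exchange relaxes to the mole-weighted equilibrium", {
  sys <- ref_system()                        # equal pools, 0.2 / 39.8 at%
  expect_equal(equilibrium_at(sys), 20)
  expect_equal(relaxation_rate(sys), 0.3)
  sol <- two_pool_solution(sys, c(0, 1000))
  expect_equal(sol$soil_at[1], 0.2)
  expect_equal(sol$soil_at[2], 20, tolerance = 1e-9)
  expect_equal(sol$external_at[2], 20, tolerance = 1e-9)
})

test_that("zero exchange flux leaves both pools constant", {
  sys <- two_pool_system(water_pool(0.01, 0.2), water_pool(0.02, 39.8), 0)
  sol <- two_pool_solution(sys, c(0, 5, 24))
  expect_equal(sol$soil_at, rep(0.2, 3))
  expect_equal(sol$external_at, rep(39.8, 3))
})

test_that("total 18O is conserved along the trajectories", {
  set.seed(71)
  for (rep in 1:25) {
    ms <- stats::runif(1, 1e-4, 0.05); me <- stats::runif(1, 1e-4, 0.05)
    sys <- two_pool_system(water_pool(ms, stats::runif(1, 0, 1)),
                           water_pool(me, stats::runif(1, 10, 99)),
                           stats::runif(1, 0, 0.02))
    sol <- two_pool_solution(sys, seq(0, 48, by = 4))
    total <- ms * atom_fraction(sol$soil_at) +
      me * atom_fraction(sol$external_at)
    expect_equal(total, rep(total[1], length(total)), tolerance = 1e-12)
  }
})

test_that("numeric integration matches the analytic solution", {
  set.seed(72)
  for (rep in 1:5) {
    sys <- two_pool_system(water_pool(stats::runif(1, 1e-3, 0.05), 0.2),
                           water_pool(stats::runif(1, 1e-3, 0.05),
                                      stats::runif(1, 20, 99)),
                           stats::runif(1, 1e-4, 0.01))
    tt <- c(2, 4, 8, 16, 24)
    num <- two_pool_numeric(sys, tt)
    ana <- two_pool_solution(sys, tt)
    expect_equal(num$soil_at, ana$soil_at, tolerance = 1e-9)
    expect_equal(num$external_at, ana$external_at, tolerance = 1e-9)
  }
})

test_that("fitting noiseless simulator output recovers the shared rate", {
  sim <- simulate_two_pool(ref_system(), c(2, 4, 8, 16, 24))
  soil <- sim$data[sim$data$pool == "soil", ]
  f <- fit_equilibration(soil$time_h, soil$atom_pct)
  expect_equal(f$b, 0.3, tolerance = 1e-6)
  expect_equal(f$at_24, 20, tolerance = 1e-6)
})

test_that("simulate_two_pool validates input and seeds its noise", {
  sys <- ref_system()
  expect_error(simulate_two_pool(sys, numeric(0)), "length >= 1")
  expect_error(simulate_two_pool(sys, c(4, 2)), "sorted")
  expect_error(simulate_two_pool(sys, c(2, 4), noise_sd = -1), ">= 0")
  a <- simulate_two_pool(sys, c(2, 4, 8), noise_sd = 0.3, replicates = 3,
                         seed = 99)
  b <- simulate_two_pool(sys, c(2, 4, 8), noise_sd = 0.3, replicates = 3,
                         seed = 99)
  expect_identical(a$data, b$data)
})

test_that("the generator is byte-identical across runs with one seed", {
  s1 <- simulate_birch_experiment(synthetic_truth(seed = 5), replicates = 2)
  s2 <- simulate_birch_experiment(synthetic_truth(seed = 5), replicates = 2)
  expect_identical(s1$kinetics, s2$kinetics)
  expect_identical(s1$endpoints, s2$endpoints)
  expect_identical(s1$truth$vials, s2$truth$vials)
  s3 <- simulate_birch_experiment(synthetic_truth(seed = 6), replicates = 2)
  expect_false(identical(s1$endpoints, s3$endpoints))
})

test_that("generator design arguments are validated", {
  expect_error(simulate_birch_experiment(synthetic_truth(),
                                         treatments = "spray"), "unknown")
  expect_error(simulate_birch_experiment(synthetic_truth(),
                                         moisture_levels = "damp"),
               "unknown")
  expect_error(synthetic_truth(rewet_resp_mult = 0.5), ">= 1")
  expect_error(synthetic_truth(true_growth = 0, true_respiration = 0),
               "not both zero")
})

test_that("noiseless pipeline recovers the configured truth exactly", {
  truth <- synthetic_truth(noise_sd_at = 0, noise_sd_ppm = 0,
                           noise_sd_at_dna = 0, seed = 8)
  sim <- simulate_birch_experiment(truth)
  fr <- fit_kinetics_table(sim$kinetics)
  expect_true(all(fr$converged))
  fl <- compute_fluxes(sim$endpoints, sim$soils, fr)
  tv <- merge(fl, sim$truth$vials, by = "vial_id")
  lab <- tv[tv$treatment != "control", ]
  expect_equal(lab$cue, lab$cue_true, tolerance = 1e-10)
  expect_equal(lab$respiration, lab$resp_true, tolerance = 1e-10)
  expect_equal(lab$growth, lab$growth_true, tolerance = 1e-8)
})

test_that("null rewetting effect makes vapor and liquid arms agree", {
  truth <- synthetic_truth(rewet_resp_mult = 1, rewet_growth_mult = 1,
                           noise_sd_at = 0, noise_sd_ppm = 0,
                           noise_sd_at_dna = 0, seed = 9)
  sim <- simulate_birch_experiment(truth, moisture_levels = "dry",
                                   treatments = c("vapor", "liquid_high"))
  fr <- fit_kinetics_table(sim$kinetics)
  fl <- compute_fluxes(sim$endpoints, sim$soils, fr)
  cmp <- compare_methods(fl)
  expect_equal(cmp$percent_diff, rep(0, nrow(cmp)), tolerance = 1e-8)
})

test_that("rewetting multipliers propagate to the comparison table", {
  truth <- synthetic_truth(rewet_resp_mult = 4.5, rewet_growth_mult = 2.8,
                           noise_sd_at = 0, noise_sd_ppm = 0,
                           noise_sd_at_dna = 0, seed = 10)
  sim <- simulate_birch_experiment(truth)
  fr <- fit_kinetics_table(sim$kinetics)
  fl <- compute_fluxes(sim$endpoints, sim$soils, fr)
  cmp <- compare_methods(fl)
  dry <- cmp[cmp$moisture == "dry", ]
  expect_equal(dry$percent_diff[dry$variable == "respiration"],
               rep(350, 3), tolerance = 1e-8)
  expect_equal(dry$percent_diff[dry$variable == "growth"],
               rep(180, 3), tolerance = 1e-8)
  expect_true(all(dry$percent_diff[dry$variable == "cue"] < 0))
  # moist arms are not rewetting-stimulated
  moist <- cmp[cmp$moisture == "moist", ]
  expect_equal(moist$percent_diff, rep(0, nrow(moist)), tolerance = 1e-8)
})

test_that("DNA enrichment synthesis inverts the production equation", {
  truth <- synthetic_truth(noise_sd_at = 0, noise_sd_ppm = 0,
                           noise_sd_at_dna = 0, seed = 12)
  sim <- simulate_birch_experiment(truth, moisture_levels = "dry",
                                   treatments = "liquid_high",
                                   replicates = 1)
  e <- sim$endpoints[1, ]
  tr <- sim$truth$vials[1, ]
  expect_equal(
    dna_produced(e$o_dna_ug, e$at_dna_label, e$at_dna_na, e$at_soil_water),
    tr$dna_produced_true, tolerance = 1e-10)
})
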