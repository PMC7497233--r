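# Negative-exponential equilibration model: prediction, fitting, time
# averaging, enrichment fraction, indirect soil-water model.

test_that("predict evaluates the equilibration curve", {
  m <- ref_model()
  expect_equal(predict(m, 0), 0.2)
  expect_equal(predict(m, 1e6), 20)                      # asymptote
  expect_equal(predict(m, 8), 20 + (0.2 - 20) * exp(-2.4),
               tolerance = 1e-12)                        # hand evaluation
  expect_error(predict(m, -1), "non-negative")
})

test_that("prediction is monotone and bounded between at_in and at_24", {
  set.seed(11)
  for (rep in 1:20) {
    at_in <- stats::runif(1, 0, 100); at_24 <- stats::runif(1, 0, 100)
    if (at_in == at_24) next
    m <- equilibration_model(at_in, at_24, stats::runif(1, 0.01, 5))
    y <- predict(m, seq(0, 48, by = 0.5))
    # monotone toward the plateau (ties allowed once the exponential
    # underflows), with a strictly moving first step
    if (at_in < at_24) {
      expect_true(all(diff(y) >= 0) && diff(y)[1] > 0)
    } else {
      expect_true(all(diff(y) <= 0) && diff(y)[1] < 0)
    }
    avg <- time_average(m)
    expect_gt(avg, min(at_in, at_24))
    expect_lt(avg, max(at_in, at_24))
  }
})

test_that("time_average has the correct limits and closed form", {
  expect_equal(time_average(equilibration_model(0.2, 20, 1e6)), 20,
               tolerance = 1e-4)                 # fast equilibration
  expect_equal(time_average(equilibration_model(0.2, 20, 1e-9)), 0.2,
               tolerance = 1e-4)                 # no exchange
  m <- ref_model()
  expect_equal(time_average(m), quadrature_average(m), tolerance = 1e-10)
  expect_equal(time_average(m), 17.252, tolerance = 1e-4)
})

test_that("closed-form average equals quadrature over random parameters", {
  set.seed(21)
  for (rep in 1:100) {
    m <- equilibration_model(stats::runif(1, 0, 100),
                             stats::runif(1, 0, 100),
                             stats::runif(1, 0.01, 5),
                             horizon_h = stats::runif(1, 6, 48))
    expect_equal(time_average(m), quadrature_average(m), tolerance = 1e-8)
  }
})

test_that("time_average is monotone in b toward the plateau", {
  b_grid <- c(0.05, 0.1, 0.3, 0.6, 1, 2)
  avgs <- vapply(b_grid, function(b) time_average(ref_model(b = b)),
                 numeric(1))
  expect_true(all(diff(avgs) > 0))   # increasing curve: faster b -> closer to 20
})

test_that("fitting noiseless data recovers the generating parameters", {
  tt <- rep(c(2, 4, 8, 16, 24), each = 3)
  for (b in c(0.05, 0.12, 0.3, 0.6, 1, 2)) {
    m <- ref_model(b = b)
    f <- fit_equilibration(tt, predict(m, tt))
    expect_true(f$converged)
    expect_equal(f$at_in, m$at_in, tolerance = 1e-6)
    expect_equal(f$at_24, m$at_24, tolerance = 1e-6)
    expect_equal(f$b, m$b, tolerance = 1e-6)
  }
})

test_that("fitting rejects degenerate and insufficient series", {
  expect_error(fit_equilibration(c(2, 4, 8), rep(5, 3)), "degenerate")
  expect_error(fit_equilibration(c(2, 4), c(1, 2)), "3 distinct")
  # two distinct times suffice when at_in is fixed
  m <- ref_model()
  f <- fit_equilibration(c(8, 24), predict(m, c(8, 24)), at_in = 0.2)
  expect_equal(f$b, 0.3, tolerance = 1e-6)
  expect_error(fit_equilibration(c(2, 4, 8), c(1, NA, 3)), "finite")
})

test_that("noisy fits recover b and the time average within tolerance", {
  m <- ref_model()
  tt <- rep(c(2, 4, 8, 16, 24), each = 3)
  set.seed(31)
  rel_b <- rel_avg <- numeric(50)
  for (i in seq_len(50)) {
    f <- fit_equilibration(tt, predict(m, tt) + stats::rnorm(15, 0, 0.3))
    rel_b[i] <- abs(f$b - m$b) / m$b
    rel_avg[i] <- abs(time_average(f) - time_average(m)) / time_average(m)
  }
  expect_lt(stats::median(rel_b), 0.10)
  expect_lt(stats::median(rel_avg), 0.02)
})

test_that("enrichment_fraction expresses the average label exposure", {
  m <- ref_model()
  # model averaging exactly to the liquid value -> 1
  flat <- equilibration_model(20, 20 - 1e-12, 1)
  expect_equal(enrichment_fraction(flat, 20, natural_abundance = 0.2), 1,
               tolerance = 1e-6)
  expect_equal(enrichment_fraction(m, 20, natural_abundance = 0.2),
               (time_average(m) - 0.2) / 19.8, tolerance = 1e-12)
  expect_equal(enrichment_fraction(m, 20, natural_abundance = 0.2), 0.8612,
               tolerance = 1e-4)
  expect_error(enrichment_fraction(m, 0.2, natural_abundance = 0.2),
               "exceed")
  # raw-ratio mode divides the plain atom percents
  expect_equal(enrichment_fraction(m, 20, excess = FALSE),
               time_average(m) / 20, tolerance = 1e-12)
})

test_that("an unlabeled soil has enrichment fraction zero", {
  flat <- equilibration_model(0.2, 0.2 + 1e-9, 0.3)
  expect_equal(enrichment_fraction(flat, 20, natural_abundance = 0.2), 0,
               tolerance = 1e-9)
})

test_that("indirect model from the external pool matches the soil curve", {
  sim <- simulate_two_pool(ref_system(), c(2, 4, 8, 16, 24))
  ext <- sim$data[sim$data$pool == "external", ]
  ind <- indirect_soil_model(ext$time_h, ext$atom_pct, soil_at_in = 0.2)
  ts <- c(2, 4, 8, 16, 24)
  truth <- two_pool_solution(ref_system(), ts)$soil_at
  expect_equal(predict(ind, ts), truth, tolerance = 1e-6)
  expect_equal(ind$b, sim$b, tolerance = 1e-6)
  # supplied soil plateau passes through untouched
  ind2 <- indirect_soil_model(ext$time_h, ext$atom_pct, soil_at_in = 0.2,
                              soil_at_24 = 19.5)
  expect_identical(ind2$at_24, 19.5)
  # an increasing (soil-like) series is flagged
  soil <- sim$data[sim$data$pool == "soil", ]
  expect_warning(indirect_soil_model(soil$time_h, soil$atom_pct,
                                     soil_at_in = 0.2), "not decaying")
})

test_that("noisy indirect prediction tracks the direct-fit time average", {
  set.seed(51)
  sim <- simulate_two_pool(ref_system(), c(2, 4, 8, 16, 24),
                           noise_sd = 0.3, replicates = 3)
  soil <- sim$data[sim$data$pool == "soil", ]
  ext <- sim$data[sim$data$pool == "external", ]
  direct <- fit_equilibration(soil$time_h, soil$atom_pct)
  ind <- indirect_soil_model(ext$time_h, ext$atom_pct, soil_at_in = 0.2,
                             external_at_in = 39.8)
  expect_lt(abs(time_average(ind) - time_average(direct)) /
              time_average(direct), 0.02)
})

test_that("shared relaxation: external-fit b equals soil-fit b", {
  sim <- simulate_two_pool(ref_system(), c(2, 4, 8, 16, 24))
  soil <- sim$data[sim$data$pool == "soil", ]
  ext <- sim$data[sim$data$pool == "external", ]
  fs <- fit_equilibration(soil$time_h, soil$atom_pct)
  fe <- fit_equilibration(ext$time_h, ext$atom_pct)
  expect_equal(fs$b, fe$b, tolerance = 1e-6)
})
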