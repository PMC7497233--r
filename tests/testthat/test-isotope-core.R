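# Isotope units, pool mixing mass balance, calibration.

test_that("mix_pools matches mole-balance arithmetic", {
  # symmetric pools average exactly
  expect_equal(mix_pools(list(water_pool(1, 0.2), water_pool(1, 39.8))), 20)
  # single pool is the identity
  expect_equal(mix_pools(list(water_pool(1, 5))), 5)
  # hand mole balance: (0.0185*0.002 + 0.0046*0.99)/0.0231
  expected <- (0.0185 * 0.002 + 0.0046 * 0.99) / (0.0185 + 0.0046) * 100
  expect_equal(mix_pools(list(water_pool(0.0185, 0.2),
                              water_pool(0.0046, 99))),
               expected, tolerance = 1e-12)
})

test_that("mix_pools rejects invalid input", {
  expect_error(mix_pools(list()), "non-empty")
  expect_error(water_pool(0, 5), "positive")
  expect_error(water_pool(-1, 5), "positive")
  expect_error(water_pool(1, 101), "\\[0, 100\\]")
})

test_that("mixing conserves 18O and is order-independent", {
  set.seed(41)
  for (rep in 1:20) {
    pools <- random_pools(sample(1:6, 1))
    m <- vapply(pools, `[[`, numeric(1), "o_moles")
    before <- sum(vapply(pools, o18_moles, numeric(1)))
    mixed_at <- mix_pools(pools)
    after <- sum(m) * atom_fraction(mixed_at)
    expect_equal(after, before, tolerance = 1e-12)
    # permutation invariance
    expect_identical(mix_pools(pools[sample(length(pools))]), mixed_at)
  }
})

test_that("mixing is associative under pooling", {
  set.seed(42)
  for (rep in 1:10) {
    pools <- random_pools(4)
    m <- vapply(pools, `[[`, numeric(1), "o_moles")
    # pre-mix the first two into one pool, then mix with the rest
    sub <- water_pool(m[1] + m[2], mix_pools(pools[1:2]))
    expect_equal(mix_pools(c(list(sub), pools[3:4])), mix_pools(pools),
                 tolerance = 1e-12)
  }
})

test_that("volume_to_o_moles uses density and enrichment-dependent molar mass", {
  # 18.015 ul of unlabeled water at 4 degC is 1 mmol of O
  expect_equal(volume_to_o_moles(18.015, at = 0, temperature_c = 4),
               1e-3, tolerance = 1e-4)
  # hand calculation at 20 degC (density 0.998203 g/ml), 97 at%:
  # molar mass 18.015 + 2*0.97 = 19.955 g/mol
  expect_equal(volume_to_o_moles(100, at = 97, temperature_c = 20),
               100e-3 * 0.998203 / 19.955, tolerance = 1e-5)
  expect_error(volume_to_o_moles(0), "positive")
  expect_error(volume_to_o_moles(-5), "positive")
  # heavier water has fewer O moles per ul
  expect_lt(volume_to_o_moles(100, at = 99), volume_to_o_moles(100, at = 0))
})

test_that("delta and atom percent converters round-trip", {
  d <- c(-50, 0, 100, 5000)
  expect_equal(atom_percent_to_delta(delta_to_atom_percent(d)), d,
               tolerance = 1e-10)
  # delta 0 is VSMOW: ~0.2 atom percent
  expect_equal(delta_to_atom_percent(0), 0.200117, tolerance = 1e-4)
})

test_that("fit_calibration recovers known lines", {
  k <- c(1, 5, 10, 20, 40)
  ident <- fit_calibration(k, k)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)
  expect_equal(ident$n_standards, 5L)

  two <- fit_calibration(c(0, 10), c(0.5, 10.3))
  expect_equal(two$slope, 0.98, tolerance = 1e-12)
  expect_equal(two$intercept, 0.5, tolerance = 1e-12)

  expect_error(fit_calibration(c(1, 1), c(1, 2)), "equal")
  expect_error(fit_calibration(1, c(1, 2)), "length")
  expect_error(fit_calibration(numeric(0), numeric(0)), "2 standards")
})

test_that("apply_calibration inverts the fitted line and flags clipping", {
  ident <- fit_calibration(c(1, 5, 10, 20, 40), c(1, 5, 10, 20, 40))
  expect_equal(as.numeric(apply_calibration(ident, 17.3)), 17.3)

  two <- fit_calibration(c(0, 10), c(0.5, 10.3))
  expect_equal(as.numeric(apply_calibration(two, 10.3)), 10,
               tolerance = 1e-12)

  expect_warning(out <- apply_calibration(ident, -0.1), "clipped")
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "out_of_range"))
})

test_that("calibration round-trips exactly on exactly linear data", {
  set.seed(7)
  for (rep in 1:10) {
    slope <- stats::runif(1, 0.8, 1.2)
    intercept <- stats::runif(1, -1, 1)
    k <- sort(stats::runif(5, 0, 40))
    m <- slope * k + intercept
    curve <- fit_calibration(k, m)
    expect_equal(as.numeric(apply_calibration(curve, m)), k,
                 tolerance = 1e-9)
  }
})

test_that("offset-only calibration mode estimates a mean offset", {
  k <- c(1, 5, 10, 20, 40)
  curve <- fit_calibration(k, k + 0.4, mode = "offset")
  expect_equal(curve$slope, 1)
  expect_equal(curve$intercept, 0.4, tolerance = 1e-12)
  expect_equal(as.numeric(apply_calibration(curve, 10.4)), 10,
               tolerance = 1e-12)
})
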