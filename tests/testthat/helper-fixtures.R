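# Shared fixtures for the test suite: small deterministic objects built in
# code, never stored on disk.

# The reference equilibration curve used throughout: natural-abundance soil
# water relaxing to a 20 at% plateau at b = 0.3 per hour.
ref_model <- function(b = 0.3, at_in = 0.2, at_24 = 20) {
  equilibration_model(at_in = at_in, at_24 = at_24, b = b, horizon_h = 24)
}

# Symmetric two-pool system with b = 0.3 (m_s = m_e = 0.01 mol, F = 0.0015).
ref_system <- function() {
  two_pool_system(water_pool(0.01, 0.2), water_pool(0.01, 39.8),
                  exchange_rate_f = 0.0015)
}

# Independent quadrature oracle for the time average: adaptive integration
# of the model curve, never the closed form under test.
quadrature_average <- function(model, horizon = model$horizon_h) {
  stats::integrate(function(t) predict(model, t), 0, horizon,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value / horizon
}

# A random (but seeded) list of water pools.
random_pools <- function(n) {
  lapply(seq_len(n), function(i) {
    water_pool(stats::runif(1, 1e-4, 1), stats::runif(1, 0, 100))
  })
}
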