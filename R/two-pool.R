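# Closed two-pool liquid-vapor-liquid isotope exchange.
#
# Soil water (m_s mol O at fraction x_s) and an external labeled pool
# (m_e mol O at x_e) exchange oxygen through the vapor phase at a gross
# flux F (mol O per hour). The vapor is treated as a massless conduit:
# at these scales the headspace holds well under 1% of the oxygen moles.
# First-order exchange gives
#
#   dx_s/dt = (F/m_s) (x_e - x_s),   dx_e/dt = (F/m_e) (x_s - x_e)
#
# so both pools relax exponentially toward the mole-weighted equilibrium
# x_eq with the single shared rate b = F (1/m_s + 1/m_e). Equilibrium
# liquid-vapor fractionation cancels between two liquid pools at the same
# temperature and is omitted by default; `alpha` shifts the external pool's
# effective enrichment for sensitivity runs.

#' Construct a closed two-pool exchange system
#'
#' @param soil_pool,external_pool [water_pool()] objects.
#' @param exchange_rate_f gross vapor-mediated exchange flux (mol O / h).
#' @param alpha effective liquid-vapor fractionation factor applied to the
#'   external pool's equilibrium contribution (default 1 = none).
#' @return An object of class `two_pool_system`.
#' @export
two_pool_system <- function(soil_pool, external_pool, exchange_rate_f,
                            alpha = 1) {
  stopifnot(inherits(soil_pool, "water_pool"),
            inherits(external_pool, "water_pool"))
  if (!is.numeric(exchange_rate_f) || exchange_rate_f < 0 ||
      !is.finite(exchange_rate_f)) {
    stop("exchange_rate_f must be a non-negative finite flux", call. = FALSE)
  }
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  structure(list(soil = soil_pool, external = external_pool,
                 f = exchange_rate_f, alpha = alpha),
            class = "two_pool_system")
}

#' Shared relaxation rate of a two-pool system
#'
#' `b = F * (1/m_s + 1/m_e)` per hour: the single exponential rate with
#' which both pools approach isotopic equilibrium.
#'
#' @param system a [two_pool_system()].
#' @return Rate coefficient b (per hour).
#' @export
relaxation_rate <- function(system) {
  stopifnot(inherits(system, "two_pool_system"))
  system$f * (1 / system$soil$o_moles + 1 / system$external$o_moles)
}

#' Mole-weighted equilibrium enrichment of a two-pool system
#'
#' @param system a [two_pool_system()].
#' @return Equilibrium enrichment (atom percent).
#' @export
equilibrium_at <- function(system) {
  mix_pools(list(system$soil, system$external))
}

#' Analytic solution of the two-pool exchange
#'
#' Both pools relax exponentially to the common equilibrium with the shared
#' rate [relaxation_rate()]; total 18O is conserved exactly at every time.
#' With `alpha != 1` the fixed point shifts to the fractionation-weighted
#' equilibrium.
#'
#' @param system a [two_pool_system()].
#' @param times times in hours (>= 0).
#' @return A data frame with columns `time_h`, `soil_at`, `external_at`
#'   (atom percent).
#' @export
two_pool_solution <- function(system, times) {
  stopifnot(inherits(system, "two_pool_system"))
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  ms <- system$soil$o_moles; me <- system$external$o_moles
  xs0 <- system$soil$x; xe0 <- system$external$x
  a <- system$alpha
  # with fractionation, exchange drives x_s toward a*x_e; fixed point from
  # conservation ms*xs + me*xe = const and xs = a*xe
  b <- system$f * (a / ms + 1 / me)
  tot <- ms * xs0 + me * xe0
  xe_eq <- tot / (ms * a + me)
  xs_eq <- a * xe_eq
  # trajectories from the decaying difference mode d(t) = (xs - a*xe) e^-bt
  # and conservation ms*xs + me*xe = tot (valid for F = 0 too: d stays d0)
  d <- (xs0 - a * xe0) * exp(-b * times)
  xs <- xs_eq + d * (me / (ms * a + me))
  xe <- (tot - ms * xs) / me
  data.frame(time_h = times, soil_at = atom_percent(xs),
             external_at = atom_percent(xe))
}

#' Numerically integrated two-pool trajectories
#'
#' Integrates the exchange ODEs with `deSolve::lsoda` at tight tolerances;
#' used to cross-check the analytic solution.
#'
#' @param system a [two_pool_system()].
#' @param times output times in hours (will be augmented with 0).
#' @param rtol,atol integrator tolerances.
#' @return A data frame like [two_pool_solution()].
#' @export
two_pool_numeric <- function(system, times, rtol = 1e-12, atol = 1e-14) {
  stopifnot(inherits(system, "two_pool_system"))
  ms <- system$soil$o_moles; me <- system$external$o_moles
  a <- system$alpha; f <- system$f
  tt <- sort(unique(c(0, times)))
  deriv <- function(t, y, parms) {
    list(c(f / ms * (a * y[2] - y[1]), f / me * (y[1] - a * y[2])))
  }
  sol <- deSolve::ode(y = c(xs = system$soil$x, xe = system$external$x),
                      times = tt, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  sol <- as.data.frame(sol)
  keep <- sol$time %in% times
  data.frame(time_h = sol$time[keep],
             soil_at = atom_percent(pmin(pmax(sol$xs[keep], 0), 1)),
             external_at = atom_percent(pmin(pmax(sol$xe[keep], 0), 1)))
}

#' Simulate noisy observations of a two-pool exchange
#'
#' Draws replicate observations of both pools at the given times, with
#' independent Gaussian measurement noise on the atom-percent scale, and
#' exposes the analytic curves and the equivalent single-exponential
#' models for both pools.
#'
#' @param system a [two_pool_system()].
#' @param times sampling times in hours (sorted, >= 1 value).
#' @param noise_sd measurement noise sd (atom percent, >= 0).
#' @param replicates observations per pool and time point.
#' @param seed optional integer seed (local RNG state).
#' @return A list with elements `data` (data frame `pool`, `time_h`,
#'   `atom_pct`, `replicate`), `analytic` (noise-free curves at `times`),
#'   `b` (shared rate), `x_eq_at` (equilibrium, atom percent), and
#'   `soil_model` / `external_model` ([equilibration_model()]s; `NULL`
#'   when the system does not relax, i.e. F = 0).
#' @export
simulate_two_pool <- function(system, times, noise_sd = 0, replicates = 1,
                              seed = NULL) {
  stopifnot(inherits(system, "two_pool_system"))
  if (length(times) < 1L || is.unsorted(times) || any(times < 0)) {
    stop("times must be sorted, non-negative, length >= 1", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
  }
  curves <- two_pool_solution(system, times)
  b <- relaxation_rate(system)
  x_eq <- equilibrium_at(system)

  grid <- expand.grid(replicate = seq_len(replicates), time_h = times,
                      KEEP.OUT.ATTRS = FALSE)
  mk <- function(pool, truth) {
    truth_rep <- truth[match(grid$time_h, times)]
    data.frame(pool = pool, time_h = grid$time_h,
               atom_pct = truth_rep +
                 if (noise_sd > 0) stats::rnorm(nrow(grid), 0, noise_sd)
                 else 0,
               replicate = grid$replicate, stringsAsFactors = FALSE)
  }
  dat <- rbind(mk("soil", curves$soil_at), mk("external", curves$external_at))

  horizon <- max(times, 24)
  soil_model <- external_model <- NULL
  if (b > 0) {
    soil_model <- equilibration_model(atom_percent(system$soil$x), x_eq, b,
                                      horizon_h = horizon)
    external_model <- equilibration_model(atom_percent(system$external$x),
                                          x_eq, b, horizon_h = horizon)
  }
  list(data = dat, analytic = curves, b = b, x_eq_at = x_eq,
       soil_model = soil_model, external_model = external_model)
}
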