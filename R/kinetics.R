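# Equilibration kinetics of 18O in soil water.
#
# In a sealed vial, soil water and an external labeled water pool exchange
# oxygen isotopes through the vapor phase; the soil-water enrichment relaxes
# along a negative exponential
#
#   at(t) = at_24 + (at_in - at_24) * exp(-b * t)
#
# where at_in is the enrichment at t = 0, at_24 the plateau approached over
# the incubation, and b (per hour) a soil-specific rate coefficient. Because
# microbial growth integrates 18O uptake over the whole incubation, the
# quantity fed into the DNA-production calculation is the time average of
# this curve over the incubation horizon, not its endpoint.

#' Construct an equilibration model
#'
#' @param at_in enrichment at t = 0 (atom percent).
#' @param at_24 plateau enrichment approached by the curve (atom percent).
#' @param b rate coefficient (per hour, > 0).
#' @param horizon_h incubation horizon over which averages are taken
#'   (hours; default 24, configurable because vials of different volume
#'   change the kinetics and possibly the incubation design).
#' @return An object of class `equilibration_model`.
#' @examples
#' m <- equilibration_model(at_in = 0.2, at_24 = 20, b = 0.3)
#' predict(m, t = c(0, 8, 24))
#' @export
equilibration_model <- function(at_in, at_24, b, horizon_h = 24) {
  atom_fraction(at_in)   # range checks
  atom_fraction(at_24)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0) {
    stop("b must be a single positive rate (per hour)", call. = FALSE)
  }
  if (!is.numeric(horizon_h) || horizon_h <= 0) {
    stop("horizon_h must be positive", call. = FALSE)
  }
  structure(list(at_in = at_in, at_24 = at_24, b = b, horizon_h = horizon_h),
            class = "equilibration_model")
}

#' @export
print.equilibration_model <- function(x, ...) {
  cat(sprintf(
    "<equilibration_model> at_in = %.4g, at_24 = %.4g at%%, b = %.4g h^-1 (horizon %g h)\n",
    x$at_in, x$at_24, x$b, x$horizon_h))
  if (!is.null(x$converged)) {
    cat(sprintf("  fitted: n = %d, SSE = %.4g, converged = %s\n",
                x$n_obs, x$sse, x$converged))
  }
  invisible(x)
}

#' Predict enrichment at time t
#'
#' @param object an [equilibration_model()].
#' @param t time(s) in hours, >= 0.
#' @param ... unused.
#' @return Enrichment in atom percent.
#' @export
predict.equilibration_model <- function(object, t, ...) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("t must be non-negative and finite", call. = FALSE)
  }
  object$at_24 + (object$at_in - object$at_24) * exp(-object$b * t)
}

#' Time-averaged enrichment over the incubation
#'
#' Closed form of (1/T) * integral_0^T of the model curve:
#' `at_24 + (at_in - at_24) * (1 - exp(-b T)) / (b T)`. This is the soil
#' water enrichment that growing microorganisms were exposed to on average,
#' and the value used to correct the DNA-production calculation for the
#' vapor-equilibration method.
#'
#' @param model an [equilibration_model()].
#' @param horizon_h averaging horizon in hours; defaults to the model's.
#' @return Time-averaged enrichment, atom percent.
#' @examples
#' time_average(equilibration_model(0.2, 20, 0.3))  # 17.25 at%
#' @export
time_average <- function(model, horizon_h = model$horizon_h) {
  stopifnot(inherits(model, "equilibration_model"))
  if (!is.numeric(horizon_h) || horizon_h <= 0) {
    stop("horizon_h must be positive", call. = FALSE)
  }
  if (model$b <= 0) stop("b must be positive", call. = FALSE)
  bt <- model$b * horizon_h
  # -expm1(-bt)/bt is (1 - e^-bt)/bt, accurate for both tiny and huge bt
  model$at_24 + (model$at_in - model$at_24) * (-expm1(-bt) / bt)
}

#' Time-averaged enrichment as a fraction of the liquid-addition enrichment
#'
#' Expresses the vapor method's average label exposure relative to the
#' constant enrichment achieved by direct liquid addition. By default both
#' enrichments are taken in excess of natural abundance, so an unlabeled
#' soil yields 0 and a fully equilibrated one 1; set `excess = FALSE` for
#' the raw atom-percent ratio.
#'
#' @param model an [equilibration_model()].
#' @param liquid_addition_at enrichment reached by direct liquid addition
#'   (atom percent); must exceed natural abundance in excess mode.
#' @param natural_abundance background enrichment (atom percent).
#' @param excess subtract natural abundance from numerator and denominator.
#' @return A fraction in (0, 1] for any increasing equilibration curve.
#' @export
enrichment_fraction <- function(model, liquid_addition_at,
                                natural_abundance = NATURAL_ABUNDANCE_AT,
                                excess = TRUE) {
  stopifnot(inherits(model, "equilibration_model"))
  avg <- time_average(model)
  if (excess) {
    denom <- liquid_addition_at - natural_abundance
    if (!is.finite(denom) || denom <= 0) {
      stop("liquid_addition_at must exceed natural abundance", call. = FALSE)
    }
    (avg - natural_abundance) / denom
  } else {
    if (!is.finite(liquid_addition_at) || liquid_addition_at <= 0) {
      stop("liquid_addition_at must be positive", call. = FALSE)
    }
    avg / liquid_addition_at
  }
}

# Deterministic starting values: plateau from the latest observations,
# at_in from the earliest (or fixed), b from ordinary regression of
# log|(y - at_24)/(at_in - at_24)| on t using interior points.
.start_values <- function(time_h, atom_pct, at_in = NULL) {
  t_min <- min(time_h); t_max <- max(time_h)
  at24_0 <- mean(atom_pct[time_h == t_max])
  atin_0 <- if (is.null(at_in)) {
    if (any(time_h == 0)) mean(atom_pct[time_h == 0]) else
      mean(atom_pct[time_h == t_min])
  } else at_in
  span <- atin_0 - at24_0
  if (span == 0) span <- max(abs(atom_pct)) * 1e-3 + 1e-6
  z <- (atom_pct - at24_0) / span
  keep <- is.finite(z) & z > 1e-8 & time_h > 0
  b0 <- if (sum(keep) >= 2L && stats::var(time_h[keep]) > 0) {
    -unname(stats::coef(stats::lm(log(z[keep]) ~ time_h[keep]))[2])
  } else {
    1 / max(stats::median(time_h), 1e-3)
  }
  if (!is.finite(b0) || b0 <= 0) b0 <- 1 / max(stats::median(time_h), 1e-3)
  list(at_in = atin_0, at_24 = at24_0, b = min(max(b0, 1e-4), 50))
}

#' Fit the negative-exponential equilibration model
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the equilibration curve
#' to a measured time series. Replicate observations at a time point are
#' fitted as individual observations. Starting values are deterministic
#' (see Details); `at_in` may be fixed (e.g. to natural abundance for soil
#' water, or to the known label enrichment for the external pool), in which
#' case only `at_24` and `b` are estimated.
#'
#' Non-convergence is never silent: the returned object carries
#' `converged = FALSE` and downstream consumers flag it.
#'
#' @details Starting values: `at_24` from the mean at the latest time,
#'   `at_in` from the mean at the earliest (unless fixed), and `b` from a
#'   regression of `log((y - at_24)/(at_in - at_24))` on `t`.
#'
#' @param time_h observation times in hours (>= 0).
#' @param atom_pct enrichments in atom percent.
#' @param at_in optional fixed t = 0 enrichment (atom percent).
#' @param horizon_h averaging horizon stored on the model (hours).
#' @return An `equilibration_model` with extra fields `sse`, `n_obs`,
#'   `converged`, `at_in_fixed`.
#' @examples
#' t <- rep(c(2, 4, 8, 16, 24), each = 3)
#' y <- predict(equilibration_model(0.2, 20, 0.3), t)
#' fit_equilibration(t, y)
#' @export
fit_equilibration <- function(time_h, atom_pct, at_in = NULL, horizon_h = 24) {
  if (length(time_h) != length(atom_pct)) {
    stop("time_h and atom_pct must have equal length", call. = FALSE)
  }
  ok <- is.finite(time_h) & is.finite(atom_pct)
  if (!all(ok)) stop("times and enrichments must be finite", call. = FALSE)
  if (any(time_h < 0)) stop("times must be non-negative", call. = FALSE)
  n_times <- length(unique(time_h))
  need <- if (is.null(at_in)) 3L else 2L
  if (n_times < need) {
    stop(sprintf("at least %d distinct time points are required", need),
         call. = FALSE)
  }
  if (stats::sd(atom_pct) == 0) {
    stop("degenerate series: all enrichments are equal", call. = FALSE)
  }

  s <- .start_values(time_h, atom_pct, at_in)
  df <- data.frame(t = time_h, y = atom_pct)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)

  fit <- if (is.null(at_in)) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ at24 + (atin - at24) * exp(-b * t), data = df,
        start = list(atin = s$at_in, at24 = s$at_24, b = s$b),
        lower = c(0, 0, 1e-8), upper = c(100, 100, Inf), control = ctrl),
      error = function(e) e)
  } else {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ at24 + (atin0 - at24) * exp(-b * t),
        data = cbind(df, atin0 = at_in),
        start = list(at24 = s$at_24, b = s$b),
        lower = c(0, 1e-8), upper = c(100, Inf), control = ctrl),
      error = function(e) e)
  }

  if (inherits(fit, "error")) {
    warning("equilibration fit did not converge: ", conditionMessage(fit),
            call. = FALSE)
    m <- equilibration_model(min(max(s$at_in, 0), 100),
                             min(max(s$at_24, 0), 100), s$b, horizon_h)
    m$sse <- sum((atom_pct - predict(m, time_h))^2)
    m$n_obs <- length(time_h)
    m$converged <- FALSE
    m$at_in_fixed <- !is.null(at_in)
    return(m)
  }

  cf <- stats::coef(fit)
  m <- equilibration_model(
    at_in = if (is.null(at_in)) unname(cf["atin"]) else at_in,
    at_24 = unname(cf["at24"]),
    b = unname(cf["b"]),
    horizon_h = horizon_h
  )
  m$sse <- sum(stats::residuals(fit)^2)
  m$n_obs <- length(time_h)
  m$converged <- isTRUE(fit$convInfo$isConv)
  m$at_in_fixed <- !is.null(at_in)
  if (!m$converged) {
    warning("equilibration fit flagged as not converged", call. = FALSE)
  }
  m
}

#' Soil-water model predicted from external-pool measurements
#'
#' The indirect route around cryodistillation: in a closed two-pool system
#' both pools relax with the same rate coefficient b, so fitting the
#' (decaying) external labeled pool yields b and the common plateau, and the
#' soil-water curve follows once its initial enrichment is known (natural
#' abundance, unless the soil was pre-labeled). The soil plateau defaults to
#' the external fit's plateau; a measured 24-h soil value may be supplied
#' instead.
#'
#' @param time_h,atom_pct external-pool time series (atom percent).
#' @param soil_at_in initial soil-water enrichment (atom percent).
#' @param soil_at_24 optional measured soil plateau; if `NULL`, the external
#'   fit's plateau is used.
#' @param external_at_in optional known t = 0 enrichment of the external
#'   label; when given, the external fit holds it fixed (the prepared label
#'   water is measured before application, so it is an input, not a free
#'   parameter).
#' @param horizon_h averaging horizon (hours).
#' @return An `equilibration_model` for the soil water, with the external
#'   fit attached as attribute `external_fit` and a logical
#'   `external_decaying` flag.
#' @export
indirect_soil_model <- function(time_h, atom_pct, soil_at_in,
                                soil_at_24 = NULL, external_at_in = NULL,
                                horizon_h = 24) {
  ext <- fit_equilibration(time_h, atom_pct, at_in = external_at_in,
                           horizon_h = horizon_h)
  decaying <- ext$at_in > ext$at_24
  if (!decaying) {
    warning("external series is not decaying; check pool labels",
            call. = FALSE)
  }
  m <- equilibration_model(
    at_in = soil_at_in,
    at_24 = if (is.null(soil_at_24)) ext$at_24 else soil_at_24,
    b = ext$b,
    horizon_h = horizon_h
  )
  m$converged <- ext$converged
  m$at_in_fixed <- TRUE
  attr(m, "external_fit") <- ext
  attr(m, "external_decaying") <- decaying
  m
}
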