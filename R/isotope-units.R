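# Isotope units and water-pool mass balance.
#
# All internal arithmetic is done in atom fraction (18O atoms per O atom);
# atom percent appears only at I/O boundaries.

#' Natural abundance of 18O in water
#'
#' VSMOW-consistent default background enrichment of unlabeled water and
#' biomolecules, in atom percent. Overridable wherever it is consumed.
#' @export
NATURAL_ABUNDANCE_AT <- 0.2005

# 18O/16O isotope ratio of VSMOW, used by the delta converter.
VSMOW_R18 <- 0.0020052

#' Convert atom percent to atom fraction
#'
#' @param atom_percent 18O atoms per 100 O atoms, in `[0, 100]`.
#' @return Atom fraction in `[0, 1]`.
#' @export
atom_fraction <- function(atom_percent) {
  stopifnot(is.numeric(atom_percent))
  if (any(!is.finite(atom_percent)) ||
      any(atom_percent < 0) || any(atom_percent > 100)) {
    stop("atom_percent must be finite and within [0, 100]", call. = FALSE)
  }
  atom_percent / 100
}

#' Convert atom fraction to atom percent
#'
#' @param fraction atom fraction in `[0, 1]`.
#' @return Atom percent in `[0, 100]`.
#' @export
atom_percent <- function(fraction) {
  stopifnot(is.numeric(fraction))
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1)) {
    stop("atom fraction must be finite and within [0, 1]", call. = FALSE)
  }
  fraction * 100
}

#' Convert between delta notation and atom percent
#'
#' `delta_to_atom_percent()` maps a delta-18O value (per mil vs. VSMOW) to
#' atom percent via R = (delta/1000 + 1) * R_VSMOW and x = R / (1 + R);
#' `atom_percent_to_delta()` is its inverse.
#'
#' @param delta delta-18O in per mil vs. VSMOW.
#' @param at atom percent.
#' @return Atom percent, or delta in per mil.
#' @export
delta_to_atom_percent <- function(delta) {
  r <- (delta / 1000 + 1) * VSMOW_R18
  if (any(r < 0)) stop("delta implies a negative isotope ratio", call. = FALSE)
  atom_percent(r / (1 + r))
}

#' @rdname delta_to_atom_percent
#' @export
atom_percent_to_delta <- function(at) {
  x <- atom_fraction(at)
  r <- x / (1 - x)
  (r / VSMOW_R18 - 1) * 1000
}

#' Construct a water pool
#'
#' A water pool is an oxygen reservoir: an amount of oxygen (mol O) and its
#' 18O enrichment. It is the unit of all mixing and exchange mass balance.
#'
#' @param o_moles moles of oxygen in the pool (> 0).
#' @param at 18O enrichment in atom percent.
#' @return An object of class `water_pool` with elements `o_moles` and
#'   `x` (atom fraction).
#' @examples
#' water_pool(0.0046, 99)
#' @export
water_pool <- function(o_moles, at) {
  if (!is.numeric(o_moles) || length(o_moles) != 1L || !is.finite(o_moles) ||
      o_moles <= 0) {
    stop("o_moles must be a single positive finite number", call. = FALSE)
  }
  structure(list(o_moles = o_moles, x = atom_fraction(at)),
            class = "water_pool")
}

#' @export
print.water_pool <- function(x, ...) {
  cat(sprintf("<water_pool> %.6g mol O at %.6g atom%% 18O\n",
              x$o_moles, 100 * x$x))
  invisible(x)
}

#' Moles of 18O held by a water pool
#'
#' @param pool a [water_pool()].
#' @return Moles of 18O (always <= `o_moles`).
#' @export
o18_moles <- function(pool) {
  stopifnot(inherits(pool, "water_pool"))
  pool$o_moles * pool$x
}

#' Mix water pools by mole-weighted mass balance
#'
#' The enrichment of the mixture is the mole-of-oxygen-weighted mean atom
#' fraction of the input pools, so total 18O is conserved exactly. This is
#' the mass balance behind both the direct liquid-addition enrichment and
#' the equilibrium value that vapor exchange relaxes towards.
#'
#' @param pools a list of [water_pool()] objects (>= 1).
#' @return Mixture enrichment in atom percent.
#' @examples
#' mix_pools(list(water_pool(1, 0.2), water_pool(1, 39.8)))  # 20 at%
#' @export
mix_pools <- function(pools) {
  if (inherits(pools, "water_pool")) pools <- list(pools)
  if (!is.list(pools) || length(pools) == 0L) {
    stop("pools must be a non-empty list of water_pool objects", call. = FALSE)
  }
  ok <- vapply(pools, inherits, logical(1), what = "water_pool")
  if (!all(ok)) stop("all elements must be water_pool objects", call. = FALSE)
  m <- vapply(pools, `[[`, numeric(1), "o_moles")
  x <- vapply(pools, `[[`, numeric(1), "x")
  atom_percent(sum(m * x) / sum(m))
}

# Density of air-free liquid water (g/ml) from the Kell (1975) polynomial,
# valid 0-100 degC at atmospheric pressure.
water_density <- function(temperature_c) {
  t <- temperature_c
  if (any(!is.finite(t)) || any(t < 0) || any(t > 100)) {
    stop("temperature_c must be within [0, 100] degC", call. = FALSE)
  }
  (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 - 46.170461e-6 * t^3 +
     105.56302e-9 * t^4 - 280.54253e-12 * t^5) / (1 + 16.879850e-3 * t) / 1000
}

#' Convert a water volume to moles of oxygen
#'
#' Uses the liquid-water density at the stated temperature (Kell polynomial)
#' and an enrichment-dependent mean molar mass, 18.015 + 2 * x g/mol with x
#' the 18O atom fraction: at tracer-level enrichments (20-99 atom percent)
#' the two extra neutron masses per H2-18O molecule shift the molar mass
#' appreciably, so mixing is computed on moles of O, never on grams.
#'
#' @param volume_ul volume in microliters (> 0).
#' @param at 18O enrichment in atom percent (default natural abundance).
#' @param temperature_c water temperature in degC (default 20).
#' @return Moles of oxygen.
#' @examples
#' volume_to_o_moles(18.015, at = 0, temperature_c = 4)  # ~1e-3 mol O
#' @export
volume_to_o_moles <- function(volume_ul, at = NATURAL_ABUNDANCE_AT,
                              temperature_c = 20) {
  if (!is.numeric(volume_ul) || any(!is.finite(volume_ul)) ||
      any(volume_ul <= 0)) {
    stop("volume_ul must be positive", call. = FALSE)
  }
  x <- atom_fraction(at)
  mass_g <- volume_ul * 1e-3 * water_density(temperature_c)
  mass_g / (18.015 + 2 * x)
}
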