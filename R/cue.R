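# Endpoint calculus: respiration, DNA production, growth, uptake, CUE.

# Physical constants
GAS_CONSTANT <- 8.31446      # J mol^-1 K^-1
CARBON_MOLAR_MASS <- 12.011  # g mol^-1
DNA_OXYGEN_PERCENT <- 31.21  # average oxygen content of DNA, % by mass

#' Physical configuration of one incubation vial
#'
#' Defaults reflect 400 mg of sieved soil in a 1.2 ml inner plastic vial
#' inside a sealed 27 ml glass headspace vial: the effective gas volume is
#' the glass volume minus the inner vial (27 - 1.2 = 25.8 ml); the ~0.15 ml
#' of soil solids is neglected.
#'
#' @param headspace_ml effective gas volume (ml).
#' @param soil_fresh_g fresh soil mass (g).
#' @param gwc gravimetric water content, g water per g *dry* soil.
#' @param label_volume_ul volume of labeled water applied (ul).
#' @param label_at enrichment of the applied label (atom percent).
#' @param temperature_c incubation temperature (degC).
#' @param pressure_kpa headspace pressure (kPa).
#' @return An object of class `vial_config`.
#' @export
vial_config <- function(headspace_ml = 25.8, soil_fresh_g = 0.4, gwc = 0.05,
                        label_volume_ul = 0, label_at = NA_real_,
                        temperature_c = 25, pressure_kpa = 101.325) {
  if (headspace_ml <= 0) stop("headspace_ml must be positive", call. = FALSE)
  if (soil_fresh_g <= 0) stop("soil_fresh_g must be positive", call. = FALSE)
  if (gwc < 0) stop("gwc must be non-negative", call. = FALSE)
  if (pressure_kpa <= 0) stop("pressure_kpa must be positive", call. = FALSE)
  structure(list(headspace_ml = headspace_ml, soil_fresh_g = soil_fresh_g,
                 gwc = gwc, label_volume_ul = label_volume_ul,
                 label_at = label_at, temperature_c = temperature_c,
                 pressure_kpa = pressure_kpa),
            class = "vial_config")
}

#' Dry soil mass from fresh mass and water content
#'
#' `dry = fresh / (1 + gwc)` with gwc on a dry-mass basis.
#'
#' @param fresh_g fresh mass (g).
#' @param gwc gravimetric water content (g water / g dry soil).
#' @return Dry mass (g).
#' @export
dry_mass_g <- function(fresh_g, gwc) {
  if (any(fresh_g <= 0)) stop("fresh_g must be positive", call. = FALSE)
  if (any(gwc < 0)) stop("gwc must be non-negative", call. = FALSE)
  fresh_g / (1 + gwc)
}

# Total moles of gas in the headspace by the ideal gas law.
headspace_moles <- function(config) {
  p_pa <- config$pressure_kpa * 1000
  v_m3 <- config$headspace_ml * 1e-6
  p_pa * v_m3 / (GAS_CONSTANT * (config$temperature_c + 273.15))
}

#' Respiration from headspace CO2 accumulation
#'
#' Converts the CO2 mixing-ratio change over the incubation into ug of
#' respired C per g dry soil: `dppm * 1e-6 * n_headspace * 12.011e6 / dry`,
#' with the total headspace moles from the ideal gas law at the vial's
#' temperature and pressure. A negative change is physically possible
#' (measurement error, leakage) and is returned as-is with a warning; the
#' pipeline flags it.
#'
#' @param co2_ppm_t0,co2_ppm_t24 CO2 mixing ratio at the start and end of
#'   the incubation (ppm).
#' @param config a [vial_config()].
#' @return ug C per g dry soil, accumulated over the incubation.
#' @examples
#' respiration_from_headspace(450, 550, vial_config(gwc = 0.05))
#' @export
respiration_from_headspace <- function(co2_ppm_t0, co2_ppm_t24, config) {
  stopifnot(inherits(config, "vial_config"))
  if (any(co2_ppm_t0 < 0) || any(co2_ppm_t24 < 0)) {
    stop("CO2 mixing ratios must be non-negative", call. = FALSE)
  }
  dry <- dry_mass_g(config$soil_fresh_g, config$gwc)
  dppm <- co2_ppm_t24 - co2_ppm_t0
  if (any(dppm < 0)) {
    warning("negative CO2 accumulation in headspace", call. = FALSE)
  }
  mol_c <- dppm * 1e-6 * headspace_moles(config)
  mol_c * CARBON_MOLAR_MASS * 1e6 / dry
}

#' DNA produced from 18O incorporation
#'
#' `DNA_produced = O_DNAextr * ((at_label - at_na) / at_soil_water) *
#' 100 / 31.21`, where `O_DNAextr` is the total oxygen in the DNA extract,
#' the atom-percent terms are the enrichments of labeled and
#' natural-abundance DNA and of the soil water the organisms drew on, and
#' 31.21 is the average oxygen content of DNA in percent. For the vapor
#' method `at_soil_water` is the time-averaged enrichment from the kinetics
#' fit; for direct liquid addition it is the constant mixing value.
#'
#' The atom-percent terms enter as raw atom percent; `excess` mode (which
#' replaces `at_soil_water` by its natural-abundance excess) exists for
#' sensitivity analysis only.
#'
#' A negative DNA label excess is unphysical; it is clipped to zero with a
#' warning so QC can see the event while downstream growth stays >= 0.
#'
#' @param o_dna_extr_ug total oxygen in the DNA extract (ug).
#' @param at_dna_label,at_dna_na enrichment of labeled and unlabeled DNA
#'   (atom percent).
#' @param at_soil_water soil-water enrichment (atom percent, > 0).
#' @param natural_abundance used only in excess mode (atom percent).
#' @param excess use natural-abundance-excess soil water enrichment.
#' @return ug DNA produced over the incubation.
#' @examples
#' dna_produced(31.21, at_dna_label = 2.0, at_dna_na = 0.2,
#'              at_soil_water = 18)
#' @export
dna_produced <- function(o_dna_extr_ug, at_dna_label, at_dna_na,
                         at_soil_water,
                         natural_abundance = NATURAL_ABUNDANCE_AT,
                         excess = FALSE) {
  if (any(o_dna_extr_ug < 0)) {
    stop("o_dna_extr_ug must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(at_soil_water)) || any(at_soil_water <= 0)) {
    stop("at_soil_water must be positive", call. = FALSE)
  }
  denom <- if (excess) at_soil_water - natural_abundance else at_soil_water
  if (any(denom <= 0)) {
    stop("soil water enrichment must exceed natural abundance in excess mode",
         call. = FALSE)
  }
  exc <- at_dna_label - at_dna_na
  if (any(exc < 0)) {
    warning("negative DNA 18O excess clipped to zero", call. = FALSE)
    exc <- pmax(exc, 0)
  }
  o_dna_extr_ug * (exc / denom) * 100 / DNA_OXYGEN_PERCENT
}

#' Convert DNA produced to microbial biomass C produced
#'
#' Multiplies by the soil-specific ratio of microbial biomass C to DNA
#' content (f_DNA, from chloroform fumigation MBC and soil DNA content) and
#' normalizes to dry soil mass.
#'
#' @param dna_ug ug DNA produced.
#' @param f_dna microbial biomass C : DNA ratio (dimensionless, > 0).
#' @param dry_mass_g dry soil mass (g, > 0).
#' @return Growth in ug C per g dry soil.
#' @export
growth_c <- function(dna_ug, f_dna, dry_mass_g) {
  if (any(f_dna <= 0)) stop("f_dna must be positive", call. = FALSE)
  if (any(dry_mass_g <= 0)) stop("dry_mass_g must be positive", call. = FALSE)
  if (any(dna_ug < 0)) stop("dna_ug must be non-negative", call. = FALSE)
  dna_ug * f_dna / dry_mass_g
}

#' Carbon use efficiency from growth and respiration
#'
#' Uptake is the sum of the two C fluxes, `C_uptake = C_growth +
#' C_respiration`, and `CUE = C_growth / C_uptake`. When both fluxes are
#' zero CUE is undefined and reported as `NA` with an `undefined_cue` flag.
#'
#' @param growth,respiration C fluxes in ug C per g dry soil (>= 0),
#'   recycled to a common length.
#' @return A data frame with columns `growth`, `respiration`, `uptake`,
#'   `cue`, `flags`.
#' @examples
#' cue(growth = 1, respiration = 3)  # CUE 0.25
#' @export
cue <- function(growth, respiration) {
  if (any(growth < 0, na.rm = TRUE) || any(respiration < 0, na.rm = TRUE)) {
    stop("growth and respiration must be non-negative", call. = FALSE)
  }
  n <- max(length(growth), length(respiration))
  growth <- rep_len(growth, n)
  respiration <- rep_len(respiration, n)
  uptake <- growth + respiration
  eff <- ifelse(uptake > 0, growth / uptake, NA_real_)
  flags <- ifelse(is.na(eff) | uptake == 0, "undefined_cue", "")
  data.frame(growth = growth, respiration = respiration, uptake = uptake,
             cue = eff, flags = flags, stringsAsFactors = FALSE)
}

#' Compare flux estimates between two labeling methods
#'
#' Group-mean comparison of respiration, growth and CUE between two
#' treatments (e.g. direct liquid addition vs. vapor equilibration), per
#' soil and moisture level: percent difference `100 * (mean_a - mean_b) /
#' mean_b` and ratio `mean_a / mean_b`. Descriptive only — no inferential
#' statistics.
#'
#' @param fluxes a flux table as returned by [compute_fluxes()] (columns
#'   `soil_id`, `moisture`, `treatment`, and the variables).
#' @param treatment_a,treatment_b treatment labels to compare (a vs. b;
#'   b is the reference).
#' @param variables flux columns to compare.
#' @return A data frame with one row per soil x moisture x variable:
#'   `mean_a`, `mean_b`, `percent_diff`, `ratio`.
#' @export
compare_methods <- function(fluxes, treatment_a = "liquid_high",
                            treatment_b = "vapor",
                            variables = c("respiration", "growth", "cue")) {
  need <- c("soil_id", "moisture", "treatment", variables)
  miss <- setdiff(need, names(fluxes))
  if (length(miss)) {
    stop("fluxes is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  a <- fluxes[fluxes$treatment == treatment_a, , drop = FALSE]
  b <- fluxes[fluxes$treatment == treatment_b, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("empty treatment group(s): ", treatment_a, " / ", treatment_b,
         call. = FALSE)
  }
  groups <- unique(rbind(a[c("soil_id", "moisture")],
                         b[c("soil_id", "moisture")]))
  out <- list()
  for (i in seq_len(nrow(groups))) {
    gi <- groups[i, ]
    ai <- a[a$soil_id == gi$soil_id & a$moisture == gi$moisture, ]
    bi <- b[b$soil_id == gi$soil_id & b$moisture == gi$moisture, ]
    if (nrow(ai) == 0L || nrow(bi) == 0L) next
    for (v in variables) {
      ma <- mean(ai[[v]], na.rm = TRUE)
      mb <- mean(bi[[v]], na.rm = TRUE)
      if (!is.finite(mb) || mb == 0) {
        stop(sprintf("zero or missing reference mean for %s in %s/%s",
                     v, gi$soil_id, gi$moisture), call. = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(
        soil_id = gi$soil_id, moisture = gi$moisture, variable = v,
        mean_a = ma, mean_b = mb,
        percent_diff = 100 * (ma - mb) / mb, ratio = ma / mb,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "treatments") <- c(a = treatment_a, b = treatment_b)
  res
}
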