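# Synthetic Birch-effect experiment with known ground truth.
#
# Emulates the comparison design: three soils x two moisture levels x
# tracer-delivery treatments (vapor equilibration, direct liquid addition
# at high and minimal volume, and a no-water control) x replicates, over a
# 24 h incubation. Vapor arms get their soil-water enrichment from the
# closed two-pool exchange simulator; liquid arms are enriched instantly to
# the mixing value and, on dry soils, have respiration and growth inflated
# by rewetting multipliers (the Birch effect). DNA 18O observations are
# synthesized by inverting the DNA-production equation with the exact
# time-averaged enrichment, so the full pipeline can be tested for exact
# round-trip recovery of the configured truth.

#' Ground-truth parameters for the synthetic experiment
#'
#' @param true_growth,true_respiration baseline microbial C fluxes over the
#'   incubation (ug C per g dry soil per 24 h). Defaults (6 and 12) give a
#'   baseline CUE of 1/3, typical of soil 18O-CUE studies.
#' @param rewet_resp_mult,rewet_growth_mult multiplicative stimulation of
#'   respiration and growth by liquid rewetting of dry soil (>= 1).
#'   Defaults 4.5 and 2.8 place the simulated rewetting burst in the range
#'   reported for dry soils (respiration several-fold, growth two- to
#'   three-fold).
#' @param noise_sd_at measurement noise sd for water 18O (atom percent).
#' @param noise_sd_ppm measurement noise sd for headspace CO2 (ppm).
#' @param noise_sd_at_dna measurement noise sd for DNA 18O (atom percent);
#'   TC/EA-IRMS precision scale, far below the water-isotope sd.
#' @param seed single integer seed; all randomness in
#'   [simulate_birch_experiment()] derives from it.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(true_growth = 6, true_respiration = 12,
                            rewet_resp_mult = 4.5, rewet_growth_mult = 2.8,
                            noise_sd_at = 0.3, noise_sd_ppm = 5,
                            noise_sd_at_dna = 0.01, seed = 1L) {
  if (true_growth < 0 || true_respiration < 0 ||
      true_growth + true_respiration <= 0) {
    stop("fluxes must be non-negative and not both zero", call. = FALSE)
  }
  if (rewet_resp_mult < 1 || rewet_growth_mult < 1) {
    stop("rewetting multipliers must be >= 1", call. = FALSE)
  }
  if (noise_sd_at < 0 || noise_sd_ppm < 0 || noise_sd_at_dna < 0) {
    stop("noise sds must be >= 0", call. = FALSE)
  }
  structure(list(
    true_growth = true_growth, true_respiration = true_respiration,
    true_cue = true_growth / (true_growth + true_respiration),
    rewet_resp_mult = rewet_resp_mult, rewet_growth_mult = rewet_growth_mult,
    noise_sd_at = noise_sd_at, noise_sd_ppm = noise_sd_ppm,
    noise_sd_at_dna = noise_sd_at_dna, seed = as.integer(seed)),
    class = "synthetic_truth")
}

#' Default synthetic soil parameterizations
#'
#' Three soils with fast, medium and slow equilibration kinetics
#' (b = 0.6, 0.3, 0.12 per hour) qualitatively emulating a grassland, a
#' forest and an agricultural soil; water-holding capacity, moisture
#' levels, microbial biomass C and DNA content are generator choices in
#' realistic ranges (f_DNA = MBC/DNA = 20 for all three).
#'
#' @return A data frame with one row per soil: `soil_id`, `b_per_h`,
#'   `whc_g_per_g`, `gwc_dry`, `gwc_moist`, `mbc_ug_per_g`, `dna_ug_per_g`.
#' @export
default_soils <- function() {
  data.frame(
    soil_id = c("grassland", "forest", "agricultural"),
    b_per_h = c(0.6, 0.3, 0.12),
    whc_g_per_g = c(0.60, 0.50, 0.40),
    gwc_dry = c(0.05, 0.05, 0.05),
    gwc_moist = c(0.30, 0.25, 0.20),
    mbc_ug_per_g = c(800, 1200, 400),
    dna_ug_per_g = c(40, 60, 20),
    stringsAsFactors = FALSE
  )
}

# Label enrichment needed so that full mixing with the soil water hits the
# target enrichment. m_e depends weakly on the enrichment through the molar
# mass, so solve by a short fixed-point iteration.
.label_for_target <- function(m_s, na_at, volume_ul, target_at,
                              temperature_c = 25) {
  x_t <- atom_fraction(target_at)
  x_na <- atom_fraction(na_at)
  x <- x_t  # initial guess
  for (i in 1:5) {
    m_e <- volume_to_o_moles(volume_ul, at = atom_percent(x),
                             temperature_c = temperature_c)
    x_new <- (x_t * (m_s + m_e) - x_na * m_s) / m_e
    if (x_new <= x_t || x_new > 1) {
      stop("label volume too small to reach the target enrichment",
           call. = FALSE)
    }
    x <- x_new
  }
  list(at = atom_percent(x), o_moles = m_e)
}

#' Simulate a full vapor-vs-liquid Birch-effect experiment
#'
#' Generates every input table the pipeline consumes — kinetics time series,
#' endpoint measurements, and soil properties — plus a per-vial ground-truth
#' record for recovery testing. All randomness comes from the single seed in
#' `truth`; rerunning with the same configuration reproduces the tables
#' byte-for-byte.
#'
#' Design conventions: liquid water additions bring the soil to 60% of its
#' water-holding capacity at a 20 atom percent final soil-water enrichment
#' (the minimal `liquid_low` addition is 30 ul at higher enrichment, dry
#' soils only); the rewetting multipliers apply to liquid arms on dry soils
#' only; the no-water `control` arm yields respiration observations only;
#' external-pool kinetics are sampled on dry vapor arms (the indirect
#' method's measurement).
#'
#' @param truth a [synthetic_truth()].
#' @param soils a soil table as from [default_soils()].
#' @param moisture_levels subset of `c("dry", "moist")`.
#' @param treatments subset of
#'   `c("vapor", "liquid_high", "liquid_low", "control")`.
#' @param replicates vials per design cell.
#' @param soil_times,external_times sampling times (h) for soil-water and
#'   external-pool kinetics.
#' @param target_at final/equilibrium soil-water enrichment aimed for by
#'   the water additions (atom percent).
#' @param natural_abundance background enrichment (atom percent).
#' @param soil_fresh_g,headspace_ml,temperature_c,pressure_kpa,incubation_h
#'   vial physical configuration (defaults: 400 mg soil, 25.8 ml effective
#'   headspace, 25 degC, 101.325 kPa, 24 h).
#' @param ppm_t0 nominal headspace CO2 at sealing (ppm).
#' @return A list with `kinetics`, `endpoints`, `soils` (input tables as
#'   data frames) and `truth` (list: `params`, per-vial `vials`).
#' @examples
#' sim <- simulate_birch_experiment(synthetic_truth(seed = 42),
#'                                  replicates = 2)
#' head(sim$endpoints)
#' @export
simulate_birch_experiment <- function(
    truth = synthetic_truth(),
    soils = default_soils(),
    moisture_levels = c("dry", "moist"),
    treatments = c("vapor", "liquid_high", "liquid_low", "control"),
    replicates = 3,
    soil_times = c(2, 4, 8, 16, 24),
    external_times = c(2, 4, 8, 24),
    target_at = 20,
    natural_abundance = NATURAL_ABUNDANCE_AT,
    soil_fresh_g = 0.4, headspace_ml = 25.8,
    temperature_c = 25, pressure_kpa = 101.325,
    incubation_h = 24, ppm_t0 = 450) {
  stopifnot(inherits(truth, "synthetic_truth"))
  bad <- setdiff(moisture_levels, c("dry", "moist"))
  if (length(bad)) stop("unknown moisture level: ", bad[1], call. = FALSE)
  bad <- setdiff(treatments,
                 c("vapor", "liquid_high", "liquid_low", "control"))
  if (length(bad)) stop("unknown treatment: ", bad[1], call. = FALSE)
  if (nrow(soils) == 0L || replicates < 1L) {
    stop("design must be non-empty", call. = FALSE)
  }

  set.seed(truth$seed)
  noise <- function(n, sd) if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)

  kin <- list(); eps <- list(); tru <- list()
  vial_n <- 0L

  for (si in seq_len(nrow(soils))) {
    soil <- soils[si, ]
    # Label water is sized on the dry arm (volume bringing the dry soil to
    # 60% WHC, enrichment hitting target_at in the mixed dry soil water)
    # and the same water is used for the moist arms, whose mixing value is
    # correspondingly lower.
    dry_g0 <- dry_mass_g(soil_fresh_g, soil$gwc_dry)
    m_s0 <- dry_g0 * soil$gwc_dry /
      (18.015 + 2 * atom_fraction(natural_abundance))
    add_g <- (0.6 * soil$whc_g_per_g - soil$gwc_dry) * dry_g0
    vol_hi <- add_g / water_density(temperature_c) * 1e3  # ul
    lab_hi <- .label_for_target(m_s0, natural_abundance, vol_hi, target_at,
                                temperature_c)
    for (moist in moisture_levels) {
      gwc <- if (moist == "dry") soil$gwc_dry else soil$gwc_moist
      dry_g <- dry_mass_g(soil_fresh_g, gwc)
      water_g <- dry_g * gwc
      m_s <- water_g / (18.015 + 2 * atom_fraction(natural_abundance))

      sys <- two_pool_system(
        water_pool(m_s, natural_abundance),
        water_pool(lab_hi$o_moles, lab_hi$at),
        exchange_rate_f = soil$b_per_h /
          (1 / m_s + 1 / lab_hi$o_moles))
      x_eq <- equilibrium_at(sys)
      soil_curve <- equilibration_model(natural_abundance, x_eq,
                                        soil$b_per_h,
                                        horizon_h = incubation_h)
      at_sw_vapor <- time_average(soil_curve)

      config <- vial_config(headspace_ml, soil_fresh_g, gwc,
                            label_volume_ul = vol_hi, label_at = lab_hi$at,
                            temperature_c = temperature_c,
                            pressure_kpa = pressure_kpa)
      n_head <- headspace_moles(config) # total mol gas in headspace

      if ("vapor" %in% treatments) {
        # soil-water kinetics (cryodistillation series), all moistures
        sol <- two_pool_solution(sys, soil_times)
        for (r in seq_len(replicates)) {
          kin[[length(kin) + 1L]] <- data.frame(
            vial_id = sprintf("K_%s_%s_soil_r%d", soil$soil_id, moist, r),
            soil_id = soil$soil_id, moisture = moist, pool = "soil",
            time_h = soil_times,
            atom_pct = sol$soil_at +
              noise(length(soil_times), truth$noise_sd_at),
            replicate = r, batch_id = paste0(soil$soil_id, "_", moist),
            label_at = lab_hi$at, stringsAsFactors = FALSE)
        }
        # external-pool kinetics: dry arms only (the indirect measurement)
        if (moist == "dry") {
          sole <- two_pool_solution(sys, external_times)
          for (r in seq_len(replicates)) {
            kin[[length(kin) + 1L]] <- data.frame(
              vial_id = sprintf("K_%s_%s_ext_r%d", soil$soil_id, moist, r),
              soil_id = soil$soil_id, moisture = moist, pool = "external",
              time_h = external_times,
              atom_pct = sole$external_at +
                noise(length(external_times), truth$noise_sd_at),
              replicate = r, batch_id = paste0(soil$soil_id, "_", moist),
              label_at = lab_hi$at, stringsAsFactors = FALSE)
          }
        }
      }

      f_dna <- soil$mbc_ug_per_g / soil$dna_ug_per_g
      for (trt in treatments) {
        if (trt == "liquid_low" && moist != "dry") next
        rewet <- trt %in% c("liquid_high", "liquid_low") && moist == "dry"
        resp_true <- truth$true_respiration *
          (if (rewet) truth$rewet_resp_mult else 1)
        grow_true <- truth$true_growth *
          (if (rewet) truth$rewet_growth_mult else 1)
        at_sw_true <- switch(trt,
          vapor = at_sw_vapor,
          liquid_high = x_eq,      # = target_at on dry arms by construction
          liquid_low = target_at,  # 30 ul at higher enrichment, dry only
          control = NA_real_)

        for (r in seq_len(replicates)) {
          vial_n <- vial_n + 1L
          vial_id <- sprintf("V%03d_%s_%s_%s_r%d", vial_n, soil$soil_id,
                             moist, trt, r)
          dppm <- resp_true * dry_g / (CARBON_MOLAR_MASS * 1e6) / n_head * 1e6
          p0 <- ppm_t0 + noise(1, truth$noise_sd_ppm)
          p24 <- ppm_t0 + dppm + noise(1, truth$noise_sd_ppm)

          if (trt == "control") {
            o_dna <- at_l <- at_na <- NA_real_
            dna_prod <- NA_real_
          } else {
            dna_prod <- grow_true * dry_g / f_dna
            o_dna <- DNA_OXYGEN_PERCENT / 100 *
              (soil$dna_ug_per_g * dry_g + dna_prod)
            at_na <- natural_abundance + noise(1, truth$noise_sd_at_dna)
            at_l <- natural_abundance +
              dna_prod * at_sw_true * DNA_OXYGEN_PERCENT / (100 * o_dna) +
              noise(1, truth$noise_sd_at_dna)
          }

          eps[[length(eps) + 1L]] <- data.frame(
            vial_id = vial_id, treatment = trt, moisture = moist,
            soil_id = soil$soil_id, replicate = r,
            co2_ppm_t0 = p0, co2_ppm_t24 = p24,
            o_dna_ug = o_dna, at_dna_label = at_l, at_dna_na = at_na,
            at_soil_water = if (trt %in% c("liquid_high", "liquid_low"))
              at_sw_true else NA_real_,
            gwc = gwc, soil_fresh_g = soil_fresh_g,
            headspace_ml = headspace_ml, temperature_c = temperature_c,
            pressure_kpa = pressure_kpa, incubation_h = incubation_h,
            stringsAsFactors = FALSE)
          tru[[length(tru) + 1L]] <- data.frame(
            vial_id = vial_id, treatment = trt, moisture = moist,
            soil_id = soil$soil_id, replicate = r,
            b_true = soil$b_per_h,
            resp_true = resp_true, growth_true = grow_true,
            cue_true = if (trt == "control") NA_real_ else
              grow_true / (grow_true + resp_true),
            at_soil_water_true = at_sw_true,
            dna_produced_true = dna_prod,
            x_eq_at = x_eq, label_at = lab_hi$at,
            label_volume_ul = vol_hi,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  soils_out <- soils
  soils_out$f_dna <- soils_out$mbc_ug_per_g / soils_out$dna_ug_per_g
  list(
    kinetics = do.call(rbind, kin),
    endpoints = do.call(rbind, eps),
    soils = soils_out,
    truth = list(params = unclass(truth), vials = do.call(rbind, tru))
  )
}
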