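# Pipeline stages: simulate -> fit kinetics -> compute fluxes -> compare.
#
# Each stage is a plain function over data frames, plus a run_* wrapper
# that reads/writes the standard CSV files so the numbered analysis
# scripts stay thin. Given one seed the full chain is reproducible
# bit-for-bit.

#' Fit equilibration kinetics for every series in a kinetics table
#'
#' Groups the table by soil x moisture x pool and fits the
#' negative-exponential model to each series (replicates as individual
#' observations). Soil-pool fits estimate `at_in` freely (starting near
#' natural abundance); external-pool fits hold `at_in` fixed at the known
#' label enrichment when a `label_at` column is present. For each soil
#' series the report carries the time-averaged enrichment and its fraction
#' of the liquid-addition enrichment.
#'
#' @param kinetics a validated kinetics table (see [validate_kinetics()]).
#' @param liquid_addition_at enrichment achieved by direct liquid addition
#'   (atom percent), the reference for `enrichment_fraction`.
#' @param natural_abundance background enrichment (atom percent).
#' @param horizon_h averaging horizon (hours).
#' @return A data frame with one row per fitted series: `soil_id`,
#'   `moisture`, `pool`, `at_in`, `at_24`, `b`, `sse`, `n_obs`,
#'   `converged`, `time_average`, `enrichment_fraction`.
#' @export
fit_kinetics_table <- function(kinetics, liquid_addition_at = 20,
                               natural_abundance = NATURAL_ABUNDANCE_AT,
                               horizon_h = 24) {
  probs <- validate_kinetics(kinetics)
  if (length(probs)) {
    stop("invalid kinetics table:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  }
  groups <- unique(kinetics[c("soil_id", "moisture", "pool")])
  out <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    sub <- kinetics[kinetics$soil_id == g$soil_id &
                      kinetics$moisture == g$moisture &
                      kinetics$pool == g$pool, ]
    fixed_at_in <- if (g$pool == "external" && "label_at" %in% names(sub) &&
                       all(is.finite(sub$label_at))) {
      sub$label_at[1]
    } else NULL
    m <- fit_equilibration(sub$time_h, sub$atom_pct, at_in = fixed_at_in,
                           horizon_h = horizon_h)
    avg <- time_average(m)
    out[[i]] <- data.frame(
      soil_id = g$soil_id, moisture = g$moisture, pool = g$pool,
      at_in = m$at_in, at_24 = m$at_24, b = m$b, sse = m$sse,
      n_obs = m$n_obs, converged = m$converged,
      time_average = avg,
      enrichment_fraction = if (g$pool == "soil")
        enrichment_fraction(m, liquid_addition_at, natural_abundance)
      else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Compute per-vial C fluxes and CUE from endpoint measurements
#'
#' For every endpoint row: respiration from headspace CO2 accumulation;
#' for labeled arms, DNA produced from 18O incorporation, growth via
#' f_DNA, uptake and CUE. The soil-water enrichment entering the DNA
#' equation is the time-averaged value from the kinetics fit report for
#' vapor arms (logged per vial via the `at_sw_source` column) and the
#' vial's own `at_soil_water` (the known mixing value) for liquid arms.
#' Control vials yield respiration only. No input row is ever dropped:
#' every output row carries its `vial_id`, with QC `flags`
#' (`negative_delta_ppm`, `negative_dna_excess`, `nonconverged_fit`,
#' `no_dna`, `undefined_cue`).
#'
#' @param endpoints validated endpoints table.
#' @param soils validated soils table (provides f_DNA = MBC/DNA).
#' @param fit_report kinetics fit report from [fit_kinetics_table()]
#'   (required when vapor arms are present).
#' @param natural_abundance background enrichment (atom percent).
#' @return A data frame with one row per vial: identifiers, `respiration`,
#'   `growth`, `uptake`, `cue` (all per incubation), `respiration_per_h`,
#'   `growth_per_h`, `at_soil_water_used`, `at_sw_source`, `flags`.
#' @export
compute_fluxes <- function(endpoints, soils, fit_report = NULL,
                           natural_abundance = NATURAL_ABUNDANCE_AT) {
  probs <- c(validate_endpoints(endpoints), validate_soils(soils))
  if (length(probs)) {
    stop("invalid input:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  }
  f_dna <- soils$mbc_ug_per_g / soils$dna_ug_per_g
  names(f_dna) <- soils$soil_id

  out <- vector("list", nrow(endpoints))
  for (i in seq_len(nrow(endpoints))) {
    e <- endpoints[i, ]
    flags <- character(0)
    config <- vial_config(
      headspace_ml = if ("headspace_ml" %in% names(e) &&
                         is.finite(e$headspace_ml)) e$headspace_ml else 25.8,
      soil_fresh_g = if ("soil_fresh_g" %in% names(e) &&
                         is.finite(e$soil_fresh_g)) e$soil_fresh_g else 0.4,
      gwc = e$gwc,
      temperature_c = if ("temperature_c" %in% names(e) &&
                          is.finite(e$temperature_c)) e$temperature_c
                      else 25,
      pressure_kpa = if ("pressure_kpa" %in% names(e) &&
                         is.finite(e$pressure_kpa)) e$pressure_kpa
                     else 101.325)
    dry_g <- dry_mass_g(config$soil_fresh_g, config$gwc)

    resp <- withCallingHandlers(
      respiration_from_headspace(e$co2_ppm_t0, e$co2_ppm_t24, config),
      warning = function(w) {
        flags <<- c(flags, "negative_delta_ppm")
        invokeRestart("muffleWarning")
      })

    at_sw <- NA_real_; src <- NA_character_
    growth <- NA_real_
    if (e$treatment == "control" || !is.finite(e$o_dna_ug)) {
      flags <- c(flags, "no_dna")
    } else {
      if (e$treatment == "vapor") {
        if (is.null(fit_report)) {
          stop("fit_report is required for vapor-arm vials", call. = FALSE)
        }
        row <- fit_report[fit_report$soil_id == e$soil_id &
                            fit_report$moisture == e$moisture &
                            fit_report$pool == "soil", ]
        if (nrow(row) == 0L) {
          stop(sprintf("no kinetics fit for soil %s (%s)", e$soil_id,
                       e$moisture), call. = FALSE)
        }
        at_sw <- row$time_average[1]
        src <- "kinetics_time_average"
        if (!isTRUE(row$converged[1])) flags <- c(flags, "nonconverged_fit")
      } else {
        at_sw <- e$at_soil_water
        src <- "liquid_mixing_value"
        if (!is.finite(at_sw)) {
          stop(sprintf("vial %s: liquid arm without at_soil_water",
                       e$vial_id), call. = FALSE)
        }
      }
      dna <- withCallingHandlers(
        dna_produced(e$o_dna_ug, e$at_dna_label, e$at_dna_na, at_sw,
                     natural_abundance),
        warning = function(w) {
          flags <<- c(flags, "negative_dna_excess")
          invokeRestart("muffleWarning")
        })
      growth <- growth_c(dna, f_dna[[e$soil_id]], dry_g)
    }

    res <- cue(growth = if (is.finite(growth)) growth else 0,
               respiration = max(resp, 0))
    if (!is.finite(growth)) res$cue <- NA_real_
    if (nzchar(res$flags[1])) flags <- c(flags, res$flags[1])

    out[[i]] <- data.frame(
      vial_id = e$vial_id, treatment = e$treatment, moisture = e$moisture,
      soil_id = e$soil_id,
      respiration = resp,
      growth = if (is.finite(growth)) growth else NA_real_,
      uptake = if (is.finite(growth)) growth + resp else NA_real_,
      cue = res$cue,
      respiration_per_h = resp / e$incubation_h,
      growth_per_h = if (is.finite(growth)) growth / e$incubation_h
                     else NA_real_,
      at_soil_water_used = at_sw, at_sw_source = src,
      flags = paste(unique(flags), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Run the simulation stage and write its output files
#'
#' Calls [simulate_birch_experiment()] and writes `kinetics.csv`,
#' `endpoints.csv`, `soils.csv` and `truth.json` (every true parameter per
#' vial) into `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param truth a [synthetic_truth()].
#' @param ... passed to [simulate_birch_experiment()].
#' @return The simulation list, invisibly.
#' @export
run_simulate <- function(out_dir, truth = synthetic_truth(), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_birch_experiment(truth = truth, ...)
  write_table(sim$kinetics, file.path(out_dir, "kinetics.csv"))
  write_table(sim$endpoints, file.path(out_dir, "endpoints.csv"))
  write_table(sim$soils, file.path(out_dir, "soils.csv"))
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("simulate: %d kinetics obs, %d vials, %d soils -> %s",
                  nrow(sim$kinetics), nrow(sim$endpoints), nrow(sim$soils),
                  out_dir))
  invisible(sim)
}

#' Run the kinetics-fitting stage over a kinetics CSV
#'
#' @param kinetics_csv path to `kinetics.csv`.
#' @param out_csv path for the fit report CSV.
#' @param ... passed to [fit_kinetics_table()].
#' @return The fit report data frame, invisibly.
#' @export
run_fit_kinetics <- function(kinetics_csv, out_csv = NULL, ...) {
  rep <- fit_kinetics_table(read_kinetics(kinetics_csv), ...)
  if (!is.null(out_csv)) write_table(rep, out_csv)
  message(sprintf("fit-kinetics: %d series fitted (%d converged)",
                  nrow(rep), sum(rep$converged)))
  invisible(rep)
}

#' Run the flux/CUE stage over endpoint, soil and fit-report CSVs
#'
#' @param endpoints_csv,soils_csv,fit_report_csv input paths.
#' @param fluxes_csv,comparison_csv output paths (optional).
#' @param ... passed to [compute_fluxes()].
#' @return A list with `fluxes` and `comparison` data frames, invisibly.
#' @export
run_compute_cue <- function(endpoints_csv, soils_csv, fit_report_csv = NULL,
                            fluxes_csv = NULL, comparison_csv = NULL, ...) {
  fit_report <- if (!is.null(fit_report_csv)) {
    utils::read.csv(fit_report_csv, stringsAsFactors = FALSE)
  }
  fluxes <- compute_fluxes(read_endpoints(endpoints_csv),
                           read_soils(soils_csv), fit_report, ...)
  comparison <- tryCatch(compare_methods(fluxes), error = function(e) NULL)
  if (!is.null(fluxes_csv)) write_table(fluxes, fluxes_csv)
  if (!is.null(comparison) && !is.null(comparison_csv)) {
    write_table(comparison, comparison_csv)
  }
  flagged <- sum(nzchar(fluxes$flags))
  message(sprintf("compute-cue: %d vials, %d flagged", nrow(fluxes),
                  flagged))
  invisible(list(fluxes = fluxes, comparison = comparison))
}

#' Assemble a pipeline run configuration
#'
#' A single structured object holding every tunable the staged pipeline
#' uses; [run_pipeline()] echoes the effective configuration to the output
#' directory as `config.json` so a run is self-documenting and
#' reproducible from the one seed.
#'
#' @param out_dir directory for all stage outputs.
#' @param seed integer seed for the generator.
#' @param natural_abundance background 18O (atom percent).
#' @param horizon_h incubation/averaging horizon (hours).
#' @param liquid_addition_at the direct liquid-addition enrichment used as
#'   the reference for enrichment fractions (atom percent).
#' @param truth a [synthetic_truth()] (its seed is overridden by `seed`).
#' @param ... further arguments stored for [simulate_birch_experiment()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            natural_abundance = NATURAL_ABUNDANCE_AT,
                            horizon_h = 24, liquid_addition_at = 20,
                            truth = synthetic_truth(), ...) {
  if (!is.numeric(horizon_h) || horizon_h <= 0) {
    stop("horizon_h must be positive", call. = FALSE)
  }
  truth$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 natural_abundance = natural_abundance,
                 horizon_h = horizon_h,
                 liquid_addition_at = liquid_addition_at,
                 truth = truth, sim_args = list(...)),
            class = "pipeline_config")
}

#' Run the full pipeline (simulate, fit, compute, compare) from one config
#'
#' @param config a [pipeline_config()].
#' @return A list with `fit_report`, `fluxes`, `comparison`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  d <- config$out_dir
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config), file.path(d, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  do.call(run_simulate, c(list(out_dir = d, truth = config$truth),
                          config$sim_args))
  fit <- run_fit_kinetics(file.path(d, "kinetics.csv"),
                          file.path(d, "fit_report.csv"),
                          liquid_addition_at = config$liquid_addition_at,
                          natural_abundance = config$natural_abundance,
                          horizon_h = config$horizon_h)
  res <- run_compute_cue(file.path(d, "endpoints.csv"),
                         file.path(d, "soils.csv"),
                         file.path(d, "fit_report.csv"),
                         fluxes_csv = file.path(d, "fluxes.csv"),
                         comparison_csv = file.path(d, "comparison.csv"),
                         natural_abundance = config$natural_abundance)
  invisible(list(fit_report = fit, fluxes = res$fluxes,
                 comparison = res$comparison))
}
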