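# CSV schemas, validation and readers/writers.
#
# All tables are plain CSV: header row, UTF-8, "." decimal separator,
# missing values as empty fields. Validators return a character vector of
# problems (with row numbers); readers stop with the full list.

.check_cols <- function(df, required, table) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    sprintf("%s: missing column(s): %s", table, paste(miss, collapse = ", "))
  } else character(0)
}

.check_numeric <- function(df, cols, table, min = -Inf, allow_na = TRUE) {
  probs <- character(0)
  for (col in intersect(cols, names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      probs <- c(probs, sprintf("%s: column %s is not numeric", table, col))
      next
    }
    bad <- which(!is.na(v) & v < min)
    if (length(bad)) {
      probs <- c(probs, sprintf("%s: %s < %g at row(s) %s", table, col, min,
                                paste(utils::head(bad, 5), collapse = ", ")))
    }
    if (!allow_na && anyNA(v)) {
      probs <- c(probs, sprintf("%s: %s has missing values at row(s) %s",
                                table, col,
                                paste(utils::head(which(is.na(v)), 5),
                                      collapse = ", ")))
    }
  }
  probs
}

#' Validate a kinetics table
#'
#' Required columns: `vial_id`, `soil_id`, `moisture`, `pool`
#' (`soil`/`external`), `time_h` (>= 0), `atom_pct` (0-100), `replicate`.
#' Each soil x moisture x pool series needs >= 3 distinct time points to be
#' fittable with a free intercept.
#'
#' @param df a data frame.
#' @return Character vector of problems (empty when valid).
#' @export
validate_kinetics <- function(df) {
  probs <- .check_cols(df, c("vial_id", "soil_id", "moisture", "pool",
                             "time_h", "atom_pct", "replicate"), "kinetics")
  if (length(probs)) return(probs)
  if (nrow(df) == 0L) return("kinetics: no rows")
  probs <- c(probs,
             .check_numeric(df, c("time_h", "atom_pct"), "kinetics", min = 0,
                            allow_na = FALSE))
  bad <- which(!df$pool %in% c("soil", "external"))
  if (length(bad)) {
    probs <- c(probs, sprintf("kinetics: invalid pool at row(s) %s",
                              paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (is.numeric(df$atom_pct)) {
    bad <- which(df$atom_pct > 100)
    if (length(bad)) {
      probs <- c(probs, sprintf("kinetics: atom_pct > 100 at row(s) %s",
                                paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  probs
}

#' Validate an endpoints table
#'
#' Required columns: `vial_id`, `treatment` (`vapor`/`liquid_high`/
#' `liquid_low`/`control`), `moisture` (`dry`/`moist`), `soil_id`,
#' `co2_ppm_t0`, `co2_ppm_t24`, `o_dna_ug`, `at_dna_label`, `at_dna_na`,
#' `at_soil_water`, `gwc`, `incubation_h`.
#'
#' @param df a data frame.
#' @return Character vector of problems (empty when valid).
#' @export
validate_endpoints <- function(df) {
  probs <- .check_cols(df, c("vial_id", "treatment", "moisture", "soil_id",
                             "co2_ppm_t0", "co2_ppm_t24", "o_dna_ug",
                             "at_dna_label", "at_dna_na", "at_soil_water",
                             "gwc", "incubation_h"), "endpoints")
  if (length(probs)) return(probs)
  if (nrow(df) == 0L) return("endpoints: no rows")
  probs <- c(probs,
             .check_numeric(df, c("co2_ppm_t0", "co2_ppm_t24", "o_dna_ug",
                                  "gwc"), "endpoints", min = 0),
             .check_numeric(df, "incubation_h", "endpoints", min = 1e-9,
                            allow_na = FALSE))
  bad <- which(!df$treatment %in% c("vapor", "liquid_high", "liquid_low",
                                    "control"))
  if (length(bad)) {
    probs <- c(probs, sprintf("endpoints: invalid treatment at row(s) %s",
                              paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(!df$moisture %in% c("dry", "moist"))
  if (length(bad)) {
    probs <- c(probs, sprintf("endpoints: invalid moisture at row(s) %s",
                              paste(utils::head(bad, 5), collapse = ", ")))
  }
  probs
}

#' Validate a soils table
#'
#' Required columns: `soil_id`, `mbc_ug_per_g`, `dna_ug_per_g` (> 0).
#'
#' @param df a data frame.
#' @return Character vector of problems (empty when valid).
#' @export
validate_soils <- function(df) {
  probs <- .check_cols(df, c("soil_id", "mbc_ug_per_g", "dna_ug_per_g"),
                       "soils")
  if (length(probs)) return(probs)
  if (nrow(df) == 0L) return("soils: no rows")
  c(probs, .check_numeric(df, c("mbc_ug_per_g", "dna_ug_per_g"), "soils",
                          min = 1e-12, allow_na = FALSE))
}

#' Validate a calibration-standards table
#'
#' Required columns: `batch_id`, `known_atom_pct`, `measured_atom_pct`;
#' each batch needs >= 2 standards with distinct known values.
#'
#' @param df a data frame.
#' @return Character vector of problems (empty when valid).
#' @export
validate_standards <- function(df) {
  probs <- .check_cols(df, c("batch_id", "known_atom_pct",
                             "measured_atom_pct"), "standards")
  if (length(probs)) return(probs)
  if (nrow(df) == 0L) return("standards: no rows")
  probs <- .check_numeric(df, c("known_atom_pct", "measured_atom_pct"),
                          "standards", min = 0, allow_na = FALSE)
  for (b in unique(df$batch_id)) {
    k <- df$known_atom_pct[df$batch_id == b]
    if (length(k) < 2L || length(unique(k)) < 2L) {
      probs <- c(probs,
                 sprintf("standards: batch %s needs >= 2 distinct knowns", b))
    }
  }
  probs
}

.read_validated <- function(path, validator, table) {
  if (!file.exists(path)) stop(table, " file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  probs <- validator(df)
  if (length(probs)) {
    stop("invalid ", table, " table:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  }
  df
}

#' Read and validate pipeline input tables
#'
#' @param path CSV file path.
#' @return A validated data frame; invalid tables abort with the full list
#'   of schema violations (row-numbered).
#' @export
read_kinetics <- function(path) .read_validated(path, validate_kinetics,
                                                "kinetics")

#' @rdname read_kinetics
#' @export
read_endpoints <- function(path) .read_validated(path, validate_endpoints,
                                                 "endpoints")

#' @rdname read_kinetics
#' @export
read_soils <- function(path) .read_validated(path, validate_soils, "soils")

#' @rdname read_kinetics
#' @export
read_standards <- function(path) .read_validated(path, validate_standards,
                                                 "standards")

#' Write a pipeline table to CSV
#'
#' Plain CSV, no row names, missing values as empty fields; numeric values
#' keep full precision (well beyond 6 significant digits).
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
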