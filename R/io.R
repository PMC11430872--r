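#' Write drying runs as tidy CSV
#'
#' Columns: `run_id`, `temperature_C`, `time_min`, `mass_g`,
#' `bone_dry_mass_g`.
#'
#' @param runs List of [drying_run()] objects or an `rw_experiment`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_drying_runs <- function(runs, path) {
  if (inherits(runs, "rw_experiment")) runs <- runs$drying_runs
  df <- do.call(rbind, lapply(runs, function(r)
    data.frame(run_id = r$run_id, temperature_C = r$temperature_C,
               time_min = r$time_min, mass_g = r$mass_g,
               bone_dry_mass_g = r$bone_dry_mass_g)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read drying runs from tidy CSV
#'
#' Inverse of [write_drying_runs()].
#'
#' @param path CSV with columns `run_id`, `temperature_C`, `time_min`,
#'   `mass_g`, `bone_dry_mass_g`.
#' @return Named list of [drying_run()] objects.
#' @export
read_drying_runs <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "temperature_C", "time_min", "mass_g",
            "bone_dry_mass_g")
  if (!all(need %in% names(df)))
    stopf("drying-run CSV needs columns %s", paste(need, collapse = ", "))
  out <- list()
  for (id in unique(df$run_id)) {
    d <- df[df$run_id == id, ]
    d <- d[order(d$time_min), ]
    out[[id]] <- drying_run(id, d$temperature_C[1], d$time_min, d$mass_g,
                            d$bone_dry_mass_g[1])
  }
  out
}

#' Write per-run cumulative energy series as CSV
#'
#' Columns: `run_id`, `time_min`, `cum_kWh`.
#'
#' @param experiment An `rw_experiment` (or a list of energy
#'   data.frames).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_energy_series <- function(experiment, path) {
  series <- if (inherits(experiment, "rw_experiment"))
    experiment$energy_series else experiment
  write.csv(do.call(rbind, series), path, row.names = FALSE)
  invisible(path)
}

# pooled (temperature, time, mr) data frame across runs
pool_moisture_data <- function(runs, clip = TRUE) {
  do.call(rbind, lapply(runs, function(r) {
    s <- moisture_ratio(r, clip = clip)
    data.frame(run_id = r$run_id, temperature_C = s$temperature_C,
               time_min = s$time_min, mr = s$mr)
  }))
}
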