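#' Settings for diffusivity extraction
#'
#' The first-term long-time solution of Fick's second law for an infinite
#' slab gives `ln(MR) = ln(8/pi^2) - (pi^2 Deff / (4 L^2)) t`, so the
#' effective diffusivity follows from the slope of `ln(MR)` against time
#' in seconds.
#'
#' @param half_thickness_m Slab half-thickness L (m).  Default 1.5e-4
#'   (a 0.3 mm leaf); absolute diffusivities scale with L^2, the
#'   activation energy does not depend on L.
#' @param mr_floor Smallest moisture ratio included in the log
#'   regression (default 0.05): near zero, the log amplifies noise.
#' @param include_t0 Include the t = 0 sample (default `TRUE`; the
#'   intercept is free, the slab solution predicts `ln(8/pi^2)`, not 0).
#' @return Object of class `rw_diffusion_settings`.
#' @export
diffusion_settings <- function(half_thickness_m = 1.5e-4, mr_floor = 0.05,
                               include_t0 = TRUE) {
  if (half_thickness_m <= 0) stopf("half_thickness_m must be > 0")
  if (mr_floor <= 0 || mr_floor >= 1) stopf("mr_floor must be in (0, 1)")
  structure(list(half_thickness_m = half_thickness_m, mr_floor = mr_floor,
                 include_t0 = isTRUE(include_t0)),
            class = "rw_diffusion_settings")
}

#' Effective moisture diffusivity from a moisture-ratio series
#'
#' Ordinary least squares of `ln(MR)` on time (converted to seconds) over
#' the points with `MR > mr_floor`, free intercept.  The slope magnitude
#' `K1` gives `Deff = 4 L^2 K1 / pi^2`.
#'
#' @param series An `rw_moisture_series`.
#' @param settings A [diffusion_settings()] object.
#' @return Object of class `rw_diffusion_result` with `temperature_C`,
#'   `slope_per_s`, `intercept`, `deff_m2_s`, `r2_line`, `n_points`.
#' @export
deff_from_series <- function(series, settings = diffusion_settings()) {
  stopifnot(inherits(series, "rw_moisture_series"),
            inherits(settings, "rw_diffusion_settings"))
  keep <- series$mr > settings$mr_floor
  if (!settings$include_t0) keep <- keep & series$time_min > 0
  t_s <- series$time_min[keep] * 60
  lmr <- log(series$mr[keep])
  if (length(t_s) < 3)
    stopf("only %d usable points above mr_floor = %g (need >= 3)",
          length(t_s), settings$mr_floor)
  fit <- lm(lmr ~ t_s)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stopf("non-negative ln(MR) slope (%.3g); series is not drying", slope)
  K1 <- -slope
  L <- settings$half_thickness_m
  ss_tot <- sum((lmr - mean(lmr))^2)
  r2 <- if (ss_tot == 0) NA_real_ else
    1 - sum(residuals(fit)^2) / ss_tot
  structure(
    list(temperature_C = series$temperature_C, slope_per_s = slope,
         intercept = unname(coef(fit)[1]),
         deff_m2_s = 4 * L^2 * K1 / pi^2,
         r2_line = r2, n_points = length(t_s)),
    class = "rw_diffusion_result"
  )
}

#' Arrhenius fit of effective diffusivity against temperature
#'
#' Least squares of `ln(Deff)` on `1/(T + 273.15)`.  The activation
#' energy is `Ea = -slope * R` with R = 8.314 J/(mol K); the
#' pre-exponential factor is `D0 = exp(intercept)`, so
#' `Deff = D0 exp(-Ea/(R T))`.
#'
#' @param temperature_C Temperatures (degrees C), at least 3, distinct.
#' @param deff_m2_s Effective diffusivities (m^2/s), all positive.
#' @return Object of class `rw_arrhenius` with `Ea_J_per_mol`, `D0_m2_s`,
#'   `r2`, `n_temps`.
#' @export
arrhenius_fit <- function(temperature_C, deff_m2_s) {
  if (length(temperature_C) != length(deff_m2_s)) stopf("unequal lengths")
  if (anyDuplicated(temperature_C))
    stopf("duplicate temperatures; aggregate replicates first")
  if (length(temperature_C) < 3) stopf("need >= 3 temperatures")
  if (any(deff_m2_s <= 0)) stopf("all Deff must be > 0")
  invT <- 1 / (temperature_C + 273.15)
  lD <- log(deff_m2_s)
  fit <- lm(lD ~ invT)
  slope <- unname(coef(fit)[2])
  ss_tot <- sum((lD - mean(lD))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(residuals(fit)^2) / ss_tot
  structure(
    list(Ea_J_per_mol = -slope * .R_GAS,
         D0_m2_s = exp(unname(coef(fit)[1])),
         r2 = r2, n_temps = length(temperature_C)),
    class = "rw_arrhenius"
  )
}

#' @export
print.rw_arrhenius <- function(x, ...) {
  cat(sprintf("<rw_arrhenius> Ea = %.3f kJ/mol, D0 = %.4g m2/s, r2 = %s (n = %d)\n",
              x$Ea_J_per_mol / 1000, x$D0_m2_s,
              formatC(x$r2, digits = 4), x$n_temps))
  invisible(x)
}

#' Per-temperature diffusivity table
#'
#' @param results List of `rw_diffusion_result` objects.
#' @return data.frame with columns `temperature_C`, `K1_per_s`,
#'   `Deff_m2_s`, `r2`.
#' @export
diffusion_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(temperature_C = r$temperature_C, K1_per_s = -r$slope_per_s,
               Deff_m2_s = r$deff_m2_s, r2 = r$r2_line)))
}

#' @importFrom stats residuals
NULL
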