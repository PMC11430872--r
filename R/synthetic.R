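#' Configuration for the synthetic refractance-window drying experiment
#'
#' Builds and validates the parameter set for the in-silico drying
#' experiment generator.  The defaults emulate a five-temperature
#' refractance window run on mint leaves: water temperatures 50--90
#' degrees C, mass recorded every 5 minutes, initial moisture 80% wet
#' basis, Page-type drying curves `MR = exp(-k t^n)` whose rate constant
#' follows an Arrhenius law in the water temperature, and per-temperature
#' quality/color panels drawn from stated means and SDs.
#'
#' Default `k_ref_per_min` and `Ea_sim_J_per_mol` are set so the noiseless
#' drying time (first sample with MR at or below `mr_stop`) falls from
#' about 156 min at 50 degrees C to about 60 min at 90 degrees C.
#'
#' @param temperatures_C Strictly increasing water temperatures (degrees C).
#' @param replicates Replicate runs per temperature.
#' @param interval_min Sampling interval (minutes).
#' @param sample_mass_g Initial wet sample mass (g).
#' @param initial_moisture_wb_pct Initial moisture, wet basis (%).
#' @param page_n Page exponent (dimensionless).
#' @param k_ref_per_min Page rate constant at `T_ref_C` (min^-n).
#' @param Ea_sim_J_per_mol Simulated activation energy for k(T) (J/mol).
#' @param T_ref_C Reference temperature for `k_ref_per_min` (degrees C).
#' @param noise_sd_mr Additive Gaussian SD on the recorded moisture ratio.
#' @param mr_stop Noiseless moisture ratio at which a run terminates.
#' @param seed Master RNG seed; all run-level seeds derive from it.
#' @param energy_kW Mean electrical draw of the dryer (kW).
#' @param energy_jitter_sd_kW SD of the per-interval power jitter (kW).
#' @param quality_means,quality_sds Optional lists with elements `color`
#'   (data.frame `label`, `L_star`, `a_star`, `b_star`) and `quality`
#'   (data.frame `label`, `rr`, `tpc`, `tfc`, `aa_pct`, `eo_pct`) giving
#'   per-temperature panel means and SDs.  Defaults come from the shipped
#'   reference summaries ([ref_summary()]).
#' @return An object of class `rw_synthetic_config`.
#' @seealso [generate_experiment()], [generate_drying_run()]
#' @export
synthetic_config <- function(temperatures_C = c(50, 60, 70, 80, 90),
                             replicates = 3,
                             interval_min = 5,
                             sample_mass_g = 500,
                             initial_moisture_wb_pct = 80,
                             page_n = 1.1,
                             k_ref_per_min = 0.01513,
                             Ea_sim_J_per_mol = 25750,
                             T_ref_C = 50,
                             noise_sd_mr = 0.01,
                             mr_stop = 0.02,
                             seed = 42,
                             energy_kW = 0.87,
                             energy_jitter_sd_kW = 0.02,
                             quality_means = NULL,
                             quality_sds = NULL) {
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)

  chk(length(temperatures_C) >= 1 && all(diff(temperatures_C) > 0),
      "temperatures_C must be non-empty and strictly increasing")
  chk(all(temperatures_C > -273.15), "temperatures_C must be physical")
  chk(replicates >= 1, "replicates must be >= 1")
  chk(interval_min > 0, "interval_min must be > 0")
  chk(sample_mass_g > 0, "sample_mass_g must be > 0")
  chk(initial_moisture_wb_pct > 0 && initial_moisture_wb_pct < 100,
      "initial_moisture_wb_pct must be in (0, 100)")
  chk(page_n > 0, "page_n must be > 0")
  chk(k_ref_per_min > 0, "k_ref_per_min must be > 0")
  chk(Ea_sim_J_per_mol >= 0, "Ea_sim_J_per_mol must be >= 0")
  chk(noise_sd_mr >= 0, "noise_sd_mr must be >= 0")
  chk(mr_stop > 0 && mr_stop < 1, "mr_stop must be in (0, 1)")
  chk(energy_kW > 0, "energy_kW must be > 0")
  chk(energy_jitter_sd_kW >= 0, "energy_jitter_sd_kW must be >= 0")

  if (is.null(quality_means)) {
    col <- ref_summary("color"); qua <- ref_summary("quality")
    quality_means <- list(
      color = col[, c("label", "L_star", "a_star", "b_star")],
      quality = qua[, c("label", "rr", "tpc", "tfc", "aa_pct", "eo_pct")]
    )
    quality_sds <- list(
      color = data.frame(label = col$label, L_star = col$L_sd,
                         a_star = col$a_sd, b_star = col$b_sd),
      quality = data.frame(label = qua$label, rr = qua$rr_sd,
                           tpc = qua$tpc_sd, tfc = qua$tfc_sd,
                           aa_pct = qua$aa_sd, eo_pct = qua$eo_sd)
    )
  }
  sd_vals <- unlist(lapply(quality_sds, function(d)
    unlist(d[, setdiff(names(d), "label")])))
  chk(all(sd_vals >= 0, na.rm = TRUE), "all quality SDs must be >= 0")

  if (length(errs)) {
    stopf("invalid synthetic config:\n- %s", paste(errs, collapse = "\n- "))
  }

  structure(
    list(
      temperatures_C = temperatures_C, replicates = as.integer(replicates),
      interval_min = interval_min, sample_mass_g = sample_mass_g,
      initial_moisture_wb_pct = initial_moisture_wb_pct,
      page_n = page_n, k_ref_per_min = k_ref_per_min,
      Ea_sim_J_per_mol = Ea_sim_J_per_mol, T_ref_C = T_ref_C,
      noise_sd_mr = noise_sd_mr, mr_stop = mr_stop, seed = as.integer(seed),
      energy_kW = energy_kW, energy_jitter_sd_kW = energy_jitter_sd_kW,
      quality_means = quality_means, quality_sds = quality_sds
    ),
    class = "rw_synthetic_config"
  )
}

#' Arrhenius-controlled Page rate constant of the generator
#'
#' `k(T) = k_ref * exp(-Ea_sim/R * (1/(T+273.15) - 1/(T_ref+273.15)))`,
#' strictly increasing in temperature for positive activation energy.
#'
#' @param temp_C Water temperature (degrees C), above absolute zero.
#' @param cfg An [synthetic_config()] object.
#' @return Rate constant in min^-n.
#' @export
page_rate_at <- function(temp_C, cfg) {
  stopifnot(inherits(cfg, "rw_synthetic_config"))
  if (any(temp_C <= -273.15)) stopf("non-physical temperature: %g", temp_C)
  TK <- temp_C + 273.15
  TrefK <- cfg$T_ref_C + 273.15
  cfg$k_ref_per_min * exp(-cfg$Ea_sim_J_per_mol / .R_GAS * (1 / TK - 1 / TrefK))
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Hard cap on samples per generated run; generation fails rather than
# looping if mr_stop is unreachable.
.MAX_SAMPLES <- 10000L

#' Generate one synthetic drying run
#'
#' Simulates a single temperature x replicate mass series: the noiseless
#' moisture ratio follows `exp(-k(T) t^n)`, additive Gaussian noise
#' (clipped to `[0, 1]`) is applied at every sample after t = 0, and
#' masses are back-computed from the moisture ratio and the bone-dry
#' mass.  The series ends at the first sample whose noiseless MR is at or
#' below `cfg$mr_stop`.
#'
#' @param temp_C Water temperature (degrees C).
#' @param cfg An [synthetic_config()] object.
#' @param seed Integer seed for this run's noise stream.
#' @param run_id Identifier stored on the run.
#' @return A [drying_run()] object.
#' @export
generate_drying_run <- function(temp_C, cfg, seed,
                                run_id = sprintf("T%g_r1", temp_C)) {
  stopifnot(inherits(cfg, "rw_synthetic_config"))
  k <- page_rate_at(temp_C, cfg)
  n <- cfg$page_n

  # extend the grid until the noiseless curve crosses mr_stop
  n_keep <- NA_integer_
  times <- (0:(.MAX_SAMPLES - 1L)) * cfg$interval_min
  mr_true <- exp(-k * times^n)
  hit <- which(mr_true <= cfg$mr_stop)
  if (!length(hit)) {
    stopf("run did not reach mr_stop = %g within %d samples",
          cfg$mr_stop, .MAX_SAMPLES)
  }
  n_keep <- hit[1]
  times <- times[seq_len(n_keep)]
  mr_true <- mr_true[seq_len(n_keep)]

  mr <- mr_true
  if (cfg$noise_sd_mr > 0 && n_keep > 1) {
    eps <- with_seed(seed, rnorm(n_keep - 1L, 0, cfg$noise_sd_mr))
    mr[-1] <- pmin(1, pmax(0, mr_true[-1] + eps))
  }

  wb <- cfg$initial_moisture_wb_pct
  m_dry <- cfg$sample_mass_g * (1 - wb / 100)
  X0 <- wb / (100 - wb)            # initial dry-basis moisture
  mass <- m_dry * (1 + X0 * mr)    # Me = 0: X_t = MR * X0

  drying_run(run_id = run_id, temperature_C = temp_C, time_min = times,
             mass_g = mass, bone_dry_mass_g = m_dry)
}

#' Generate a complete synthetic drying experiment
#'
#' Produces one [drying_run()] per temperature x replicate, a cumulative
#' energy-meter series per run (constant mean power with seeded
#' per-interval jitter), per-temperature color and quality panels drawn
#' from the configured means and SDs, and three-phase rehydration curves
#' (fast uptake, slowdown, plateau).  All randomness derives from
#' `cfg$seed` through per-run sub-seeds, so adding replicates never
#' perturbs existing runs.
#'
#' @param cfg An [synthetic_config()] object.
#' @return An object of class `rw_experiment` with elements
#'   `drying_runs`, `energy_series`, `color_panel`, `quality_panel`,
#'   `rehydration_series`, `config`.
#' @export
generate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "rw_synthetic_config"))
  temps <- cfg$temperatures_C

  runs <- list(); energy <- list()
  for (ti in seq_along(temps)) {
    for (ri in seq_len(cfg$replicates)) {
      id <- sprintf("T%g_r%d", temps[ti], ri)
      run <- generate_drying_run(
        temps[ti], cfg, seed = derive_seed(cfg$seed, 1L, ti, ri), run_id = id
      )
      runs[[id]] <- run
      nt <- length(run$time_min)
      jit <- with_seed(
        derive_seed(cfg$seed, 2L, ti, ri),
        rnorm(max(nt - 1L, 0L), 0, cfg$energy_jitter_sd_kW)
      )
      p_kW <- pmax(cfg$energy_kW + jit, 0)
      cum <- c(0, cumsum(p_kW * cfg$interval_min / 60))
      energy[[id]] <- data.frame(run_id = id, time_min = run$time_min,
                                 cum_kWh = cum[seq_len(nt)])
    }
  }

  qm <- cfg$quality_means; qs <- cfg$quality_sds
  draw_panel <- function(means, sds, tag) {
    out <- list()
    for (i in seq_len(nrow(means))) {
      lab <- means$label[i]
      n_rep <- if (identical(lab, "fresh")) 1L else cfg$replicates
      cols <- setdiff(names(means), "label")
      vals <- with_seed(
        derive_seed(cfg$seed, tag, i),
        vapply(cols, function(cl) {
          mu <- means[[cl]][i]
          s <- sds[[cl]][match(lab, sds$label)]
          if (is.na(mu)) return(rep(NA_real_, n_rep))
          if (is.na(s) || s == 0) rep(mu, n_rep) else rnorm(n_rep, mu, s)
        }, numeric(n_rep))
      )
      vals <- matrix(vals, nrow = n_rep,
                     dimnames = list(NULL, cols))
      out[[i]] <- data.frame(label = lab, replicate = seq_len(n_rep), vals,
                             row.names = NULL)
    }
    do.call(rbind, out)
  }
  color_panel <- draw_panel(qm$color, qs$color, 3L)
  quality_panel <- draw_panel(qm$quality, qs$quality, 4L)

  # three-phase rehydration: RR(t) = 1 + (plateau-1)(1 - exp(-(t/55)^1.4)),
  # plateau from the quality panel means, 4 g dried subsample soaked
  soak <- seq(0, 180, by = 30)
  reh <- list()
  qrows <- qm$quality[qm$quality$label != "fresh", ]
  for (i in seq_len(nrow(qrows))) {
    plateau <- qrows$rr[i]
    for (ri in seq_len(cfg$replicates)) {
      fac <- with_seed(derive_seed(cfg$seed, 5L, i, ri),
                       exp(rnorm(1, 0, 0.02)))
      rr <- 1 + (plateau - 1) * fac * (1 - exp(-(soak / 55)^1.4))
      reh[[length(reh) + 1L]] <- data.frame(
        temperature_C = as.numeric(qrows$label[i]), replicate = ri,
        time_min = soak, rehydrated_mass_g = 4 * rr
      )
    }
  }

  structure(
    list(drying_runs = runs, energy_series = energy,
         color_panel = color_panel, quality_panel = quality_panel,
         rehydration_series = do.call(rbind, reh), config = cfg),
    class = "rw_experiment"
  )
}

#' @export
print.rw_experiment <- function(x, ...) {
  cat(sprintf(
    "<rw_experiment> %d drying runs (%d temperatures x %d replicates)\n",
    length(x$drying_runs), length(x$config$temperatures_C),
    x$config$replicates
  ))
  invisible(x)
}
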