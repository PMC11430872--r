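#' Validate a pipeline configuration
#'
#' Accepts a nested list, or a path to a YAML/JSON document, and returns
#' a fully defaulted, validated run configuration.  Unknown keys are
#' rejected and all schema violations are reported together, not just
#' the first.
#'
#' Recognized top-level keys: `input` (`mode = "synthetic"` or `"csv"`,
#' plus `drying_csv`/`energy_csv` paths for csv mode), `synthetic`
#' (arguments of [synthetic_config()]), `diffusion`
#' ([diffusion_settings()]), `emissions` ([emission_settings()]),
#' `training` ([train_config()]), `ann` (`hidden`, `activations`,
#' `search`), `outdir`, `seed`, `mr_target`.
#'
#' @param raw List, or path to a `.yml`/`.yaml`/`.json` file.
#' @return Object of class `rw_run_config`.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1) {
    raw <- if (grepl("\\.ya?ml$", raw)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stopf("the 'yaml' package is required to read YAML configs")
      yaml::read_yaml(raw)
    } else jsonlite::read_json(raw, simplifyVector = TRUE)
  }
  if (!is.list(raw)) stopf("config must be a list or a file path")

  errs <- character()
  known <- c("input", "synthetic", "diffusion", "emissions", "training",
             "ann", "outdir", "seed", "mr_target")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    errs <- c(errs, sprintf("unknown top-level key(s): %s",
                            paste(extra, collapse = ", ")))

  seed <- raw$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1)
    errs <- c(errs, "seed must be a single integer")

  input <- raw$input %||% list(mode = "synthetic")
  mode <- input$mode %||% "synthetic"
  if (!mode %in% c("synthetic", "csv"))
    errs <- c(errs, "input$mode must be 'synthetic' or 'csv'")
  if (identical(mode, "csv") && is.null(input$drying_csv))
    errs <- c(errs, "input$drying_csv required in csv mode")

  mr_target <- raw$mr_target %||% 0.05
  if (!is.numeric(mr_target) || mr_target <= 0 || mr_target >= 1)
    errs <- c(errs, "mr_target must be in (0, 1)")

  build <- function(fn, args, label) {
    tryCatch(do.call(fn, as.list(args %||% list())), error = function(e) {
      errs <<- c(errs, sprintf("%s: %s", label, conditionMessage(e)))
      NULL
    })
  }
  syn_args <- as.list(raw$synthetic %||% list())
  syn_args$seed <- syn_args$seed %||%
    derive_seed(as.integer(seed), stage_tag("synthetic"))
  synthetic <- build(synthetic_config, syn_args, "synthetic")
  diffusion <- build(diffusion_settings, raw$diffusion, "diffusion")
  emissions <- build(emission_settings, raw$emissions, "emissions")
  tr_args <- as.list(raw$training %||% list())
  tr_args$seed <- tr_args$seed %||%
    derive_seed(as.integer(seed), stage_tag("training"))
  training <- build(train_config, tr_args, "training")

  ann <- raw$ann %||% list()
  ann_extra <- setdiff(names(ann), c("hidden", "activations", "search",
                                     "hidden_range", "activation_sets"))
  if (length(ann_extra))
    errs <- c(errs, sprintf("unknown ann key(s): %s",
                            paste(ann_extra, collapse = ", ")))
  ann$hidden <- ann$hidden %||% c(15, 14)
  ann$activations <- ann$activations %||% c("tansig", "logsig", "purelin")
  ann$search <- isTRUE(ann$search)
  topo <- build(ann_topology, list(ann$hidden, ann$activations), "ann")

  if (length(errs))
    stopf("invalid configuration:\n- %s", paste(errs, collapse = "\n- "))

  structure(
    list(input = list(mode = mode, drying_csv = input$drying_csv,
                      energy_csv = input$energy_csv),
         synthetic = synthetic, diffusion = diffusion,
         emissions = emissions, training = training,
         ann = ann, ann_topology = topo,
         outdir = raw$outdir %||% tempfile("rwdry_run_"),
         seed = as.integer(seed), mr_target = mr_target),
    class = "rw_run_config"
  )
}

.write_table <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full drying-analysis pipeline
#'
#' Generates (or ingests) drying data, then runs the analysis chain:
#' moisture-ratio kinetics and six-model fitting, diffusivity and
#' Arrhenius activation energy, transition-state thermodynamics,
#' energy/emission accounting, quality summaries, Levenberg--Marquardt
#' network training, and the network-vs-kinetic comparison.  All stage
#' tables are written as CSV under `config$outdir` and a machine-readable
#' report (JSON) collects headline numbers, file paths and seeds.  The
#' run is idempotent for a fixed seed.
#'
#' @param config An `rw_run_config` from [validate_config()], or a raw
#'   list/path accepted by it.
#' @return The report, invisibly, as a list (also written to
#'   `report.json`).
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "rw_run_config")) config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  # --- data ---------------------------------------------------------
  experiment <- NULL
  if (config$input$mode == "synthetic") {
    experiment <- generate_experiment(config$synthetic)
    runs <- experiment$drying_runs
    energy_series <- experiment$energy_series
    paths$drying_runs <- write_drying_runs(
      runs, file.path(outdir, "drying_runs.csv"))
    paths$energy_series <- write_energy_series(
      experiment, file.path(outdir, "energy_series.csv"))
  } else {
    runs <- read_drying_runs(config$input$drying_csv)
    energy_series <- if (!is.null(config$input$energy_csv)) {
      df <- read.csv(config$input$energy_csv)
      split(df, df$run_id)
    }
  }

  # --- kinetics ------------------------------------------------------
  series <- lapply(runs, moisture_ratio)
  fits <- list()
  for (s in series) {
    for (m in thin_layer_models()) {
      fits[[paste(s$run_id, m, sep = ".")]] <-
        fit_thin_layer_model(s, m)
    }
  }
  ftab <- fit_table(fits)
  paths$fits <- .write_table(ftab, file.path(outdir, "fits.csv"))
  mean_r2 <- aggregate(r2 ~ model, data = ftab[ftab$converged, ], FUN = mean)
  best_model <- mean_r2$model[which.max(mean_r2$r2)]

  # --- diffusion + Arrhenius ----------------------------------------
  dres <- lapply(series, deff_from_series, settings = config$diffusion)
  dtab <- diffusion_table(dres)
  dmean <- aggregate(Deff_m2_s ~ temperature_C, data = dtab, FUN = mean)
  arr <- arrhenius_fit(dmean$temperature_C, dmean$Deff_m2_s)
  paths$diffusion <- .write_table(dtab, file.path(outdir, "diffusion.csv"))

  # --- thermodynamics ------------------------------------------------
  ttab <- thermo_table(arr, dmean$temperature_C)
  paths$thermo <- .write_table(ttab, file.path(outdir, "thermo.csv"))

  # --- energy + emissions -------------------------------------------
  etab <- percent_changes <- NULL
  if (!is.null(energy_series)) {
    recs <- lapply(names(runs), function(id) {
      r <- runs[[id]]
      es <- energy_series[[id]]
      wr <- (r$mass_g[1] - r$mass_g[length(r$mass_g)]) / 1000
      rec <- energy_record(r$temperature_C, max(es$cum_kWh), wr,
                           config$emissions)
      rec$drying_time_min <- max(r$time_min)
      rec
    })
    per_run <- do.call(rbind, recs)
    etab <- aggregate(
      cbind(total_kWh, water_removed_kg, sec_kWh_per_kg,
            sec_real_kWh_per_kg, co2_kg_per_kg, nox_kg_per_kg,
            drying_time_min) ~ temperature_C,
      data = per_run, FUN = mean)
    paths$energy <- .write_table(etab, file.path(outdir, "energy.csv"))
    lo <- which.min(etab$temperature_C); hi <- which.max(etab$temperature_C)
    percent_changes <- list(
      drying_time_pct = percent_change(etab$drying_time_min[lo],
                                       etab$drying_time_min[hi]),
      sec_pct = percent_change(etab$sec_kWh_per_kg[lo],
                               etab$sec_kWh_per_kg[hi]),
      co2_pct = percent_change(etab$co2_kg_per_kg[lo],
                               etab$co2_kg_per_kg[hi]),
      nox_pct = percent_change(etab$nox_kg_per_kg[lo],
                               etab$nox_kg_per_kg[hi])
    )
  }

  # --- quality -------------------------------------------------------
  quality_summary <- color_summary <- NULL
  if (!is.null(experiment)) {
    cp <- experiment$color_panel
    fresh_mean <- colMeans(cp[cp$label == "fresh",
                              c("L_star", "a_star", "b_star")])
    cp$chroma <- chroma(cp$a_star, cp$b_star)
    cp$delta_e <- vapply(seq_len(nrow(cp)), function(i)
      delta_e(fresh_mean, unlist(cp[i, c("L_star", "a_star", "b_star")])),
      0)
    cp$delta_e[cp$label == "fresh"] <- NA_real_
    color_summary <- summarize_panel(cp)
    paths$color <- .write_table(color_summary,
                                file.path(outdir, "color_summary.csv"))
    quality_summary <- summarize_panel(experiment$quality_panel)
    paths$quality <- .write_table(quality_summary,
                                  file.path(outdir, "quality_summary.csv"))
  }

  # --- neural network ------------------------------------------------
  pooled <- pool_moisture_data(runs)
  net <- build_network(config$ann_topology,
                       seed = derive_seed(config$seed, stage_tag("ann")))
  ann <- train_lm(net, pooled, config$training)
  paths$ann_model <- write_ann_json(ann, file.path(outdir, "ann_model.json"))

  # compare on the median-temperature run against the best kinetic model
  temps <- sort(unique(vapply(runs, `[[`, 0, "temperature_C")))
  mid_t <- temps[ceiling(length(temps) / 2)]
  mid_run <- runs[[which(vapply(runs, `[[`, 0, "temperature_C") == mid_t)[1]]]
  mid_series <- moisture_ratio(mid_run)
  best_fit <- fit_thin_layer_model(mid_series, best_model)
  comparison <- compare_models(
    ann, best_fit,
    data.frame(temperature_C = mid_t, time_min = mid_series$time_min,
               mr = mid_series$mr)
  )
  paths$comparison <- .write_table(comparison$table,
                                   file.path(outdir, "comparison.csv"))

  report <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("rwdry")),
    input_mode = config$input$mode,
    files = paths,
    headline = list(
      Ea_kJ_per_mol = arr$Ea_J_per_mol / 1000,
      D0_m2_s = arr$D0_m2_s,
      arrhenius_r2 = arr$r2,
      best_kinetic_model = best_model,
      ann_topology = format(config$ann_topology),
      ann_test_mse = ann$mse,
      ann_test_r2 = ann$r2,
      comparison_winner = comparison$winner,
      percent_changes = percent_changes,
      thermo = ttab,
      energy = if (!is.null(etab))
        etab[, c("temperature_C", "sec_kWh_per_kg", "co2_kg_per_kg",
                 "nox_kg_per_kg")]
    )
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(report)
}

#' Headline numbers recomputed from the shipped reference summaries
#'
#' Runs the summary-level parts of the chain on the reference fixture
#' tables ([ref_summary()]): the Arrhenius regression over the reported
#' per-temperature diffusivities, the enthalpy/entropy/Gibbs identities,
#' chroma recomputed from the reported a*/b* means, and the
#' percent-change headlines (drying time, SEC, CO2, NOx between the
#' lowest and highest temperature; essential oil between 80 and 90
#' degrees C).
#'
#' @return Nested list of headline values.
#' @export
reference_report <- function() {
  dr <- ref_summary("drying")
  th <- ref_summary("thermo")
  co <- ref_summary("color")
  qu <- ref_summary("quality")

  arr <- arrhenius_fit(dr$temperature_C, dr$deff_m2_s)
  dH <- enthalpy(arr$Ea_J_per_mol, dr$temperature_C)
  i90 <- match(90, th$temperature_C)
  i50 <- which.min(dr$temperature_C); i90d <- which.max(dr$temperature_C)
  dried <- co[co$label != "fresh", ]
  i80 <- match("80", qu$label); i90q <- match("90", qu$label)

  list(
    arrhenius = list(Ea_kJ_per_mol = arr$Ea_J_per_mol / 1000,
                     D0_m2_s = arr$D0_m2_s, r2 = arr$r2),
    enthalpy_kJ_per_mol = setNames(dH, dr$temperature_C),
    gibbs_identity_kJ_per_mol = setNames(
      gibbs(th$dH_kJ_per_mol, th$dS_kJ_per_molK, th$temperature_C),
      th$temperature_C),
    gibbs_90C = gibbs(th$dH_kJ_per_mol[i90], th$dS_kJ_per_molK[i90], 90),
    enthalpy_90C = enthalpy(arr$Ea_J_per_mol, 90),
    chroma = setNames(chroma(dried$a_star, dried$b_star), dried$label),
    percent_changes = list(
      drying_time_pct = percent_change(dr$drying_time_min[i50],
                                       dr$drying_time_min[i90d]),
      sec_pct = percent_change(dr$sec_kWh_per_kg[i50],
                               dr$sec_kWh_per_kg[i90d]),
      co2_pct = percent_change(dr$co2_kg_per_kg[i50],
                               dr$co2_kg_per_kg[i90d]),
      nox_pct = percent_change(dr$nox_kg_per_kg[i50],
                               dr$nox_kg_per_kg[i90d]),
      eo_pct = percent_change(qu$eo_pct[i80], qu$eo_pct[i90q])
    )
  )
}
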