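test_that("page rate law anchors at the reference temperature", {
  cfg <- synthetic_config()
  expect_identical(page_rate_at(cfg$T_ref_C, cfg), cfg$k_ref_per_min)

  flat <- synthetic_config(Ea_sim_J_per_mol = 0)
  for (T in c(-40, 25, 50, 90, 200))
    expect_equal(page_rate_at(T, flat), flat$k_ref_per_min)

  expect_error(page_rate_at(-300, cfg), "non-physical")
})

test_that("page rate follows the Arrhenius expression and increases in T", {
  cfg <- synthetic_config(k_ref_per_min = 0.02, Ea_sim_J_per_mol = 25750,
                          T_ref_C = 50)
  # independent evaluation of the exponent, term by term
  exponent <- -25750 / 8.314 * (1 / (90 + 273.15) - 1 / (50 + 273.15))
  expect_equal(page_rate_at(90, cfg), 0.02 * exp(exponent), tolerance = 1e-12)

  k <- page_rate_at(seq(50, 90, 5), cfg)
  expect_true(all(diff(k) > 0))
})

test_that("noiseless runs reproduce the Page curve and start at full mass", {
  cfg <- quiet_config()
  run <- generate_drying_run(60, cfg, seed = 1)
  expect_equal(run$time_min[1], 0)
  expect_equal(run$mass_g[1], cfg$sample_mass_g)

  s <- moisture_ratio(run)
  k <- page_rate_at(60, cfg)
  expect_equal(s$mr, exp(-k * s$time_min^cfg$page_n), tolerance = 1e-12)
  expect_identical(s$mr[1], 1)
  # strictly decreasing after t = 0, bounded in (0, 1]
  expect_true(all(diff(s$mr) < 0))
  expect_true(all(s$mr > 0 & s$mr <= 1))
})

test_that("runs are bit-reproducible for a fixed seed", {
  cfg <- synthetic_config(noise_sd_mr = 0.02)
  r1 <- generate_drying_run(70, cfg, seed = 99)
  r2 <- generate_drying_run(70, cfg, seed = 99)
  expect_identical(r1, r2)

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_drying_runs(list(r1), f1); write_drying_runs(list(r2), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a run that cannot reach mr_stop fails naming the cap", {
  cfg <- synthetic_config(k_ref_per_min = 1e-9)
  expect_error(generate_drying_run(50, cfg, seed = 1), "10000")
})

test_that("experiment bundles one run per temperature x replicate", {
  ex <- generate_experiment(synthetic_config(replicates = 3))
  expect_length(ex$drying_runs, 15)
  expect_length(ex$energy_series, 15)
  expect_identical(sum(ex$color_panel$label == "fresh"), 1L)
  # cumulative energy is non-decreasing in every run
  for (es in ex$energy_series) expect_true(all(diff(es$cum_kWh) >= 0))
})

test_that("drying time is non-increasing in temperature", {
  ex <- generate_experiment(quiet_config())
  end_t <- vapply(ex$drying_runs, function(r) max(r$time_min), 0)
  temps <- vapply(ex$drying_runs, `[[`, 0, "temperature_C")
  expect_true(all(diff(end_t[order(temps)]) <= 0))
})

test_that("zero quality SDs collapse panels onto the configured means", {
  cfg <- synthetic_config(replicates = 2)
  cfg$quality_sds$color[, -1] <- 0
  cfg$quality_sds$quality[, -1] <- 0
  ex <- generate_experiment(cfg)
  for (lab in cfg$quality_means$color$label) {
    got <- ex$color_panel[ex$color_panel$label == lab, "L_star"]
    expect_true(all(got == cfg$quality_means$color$L_star[
      cfg$quality_means$color$label == lab]))
  }
  got_rr <- ex$quality_panel[ex$quality_panel$label == "50", "rr"]
  expect_true(all(got_rr == cfg$quality_means$quality$rr[
    cfg$quality_means$quality$label == "50"]))
})

test_that("rehydration curves are non-decreasing in soak time", {
  ex <- generate_experiment(synthetic_config(replicates = 2))
  reh <- ex$rehydration_series
  for (key in unique(paste(reh$temperature_C, reh$replicate))) {
    cur <- reh[paste(reh$temperature_C, reh$replicate) == key, ]
    rr <- rehydration_ratio(cur$rehydrated_mass_g, 4)
    expect_true(all(diff(rr[order(cur$time_min)]) >= 0))
  }
})

test_that("adding replicates does not perturb existing runs", {
  ex2 <- generate_experiment(synthetic_config(replicates = 2))
  ex3 <- generate_experiment(synthetic_config(replicates = 3))
  expect_identical(ex2$drying_runs[["T50_r1"]], ex3$drying_runs[["T50_r1"]])
  expect_identical(ex2$drying_runs[["T90_r2"]], ex3$drying_runs[["T90_r2"]])
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(temperatures_C = c(70, 50)), "increasing")
  expect_error(synthetic_config(mr_stop = 1.2), "mr_stop")
  expect_error(synthetic_config(noise_sd_mr = -1), "noise_sd_mr")
  expect_error(synthetic_config(replicates = 0), "replicates")
  expect_error(synthetic_config(initial_moisture_wb_pct = 100),
               "initial_moisture")
})
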