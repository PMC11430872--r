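test_that("moisture ratio follows the dry-basis normalization", {
  # 10 g at 80% w.b.: bone-dry 2 g, X0 = 4; at 6 g, X = 2, MR = 0.5
  run <- drying_run("h", 50, c(0, 10, 20), c(10, 6, 2.0001),
                    bone_dry_mass_g = 2)
  s <- moisture_ratio(run)
  expect_identical(s$mr[1], 1)
  expect_equal(s$mr[2], 0.5)
  expect_equal(s$mr[3], 0, tolerance = 1e-3)

  # invariant under uniform rescaling of masses (g -> kg)
  run_kg <- drying_run("h", 50, c(0, 10, 20), c(10, 6, 2.0001) / 1000,
                       bone_dry_mass_g = 2 / 1000)
  expect_equal(moisture_ratio(run_kg)$mr, s$mr)
})

test_that("moisture ratio rejects series already at equilibrium", {
  run <- drying_run("e", 50, c(0, 5), c(4, 4), bone_dry_mass_g = 2,
                    equilibrium_moisture_db = 1)
  expect_error(moisture_ratio(run), "Me")
})

test_that("drying-run construction validates its invariants", {
  expect_error(drying_run("x", 50, c(0, 5), c(10, 9, 8), 2), "equal length")
  expect_error(drying_run("x", 50, c(5, 10), c(10, 9), 2), "start at 0")
  expect_error(drying_run("x", 50, c(0, 5), c(10, 1), 2), "bone-dry")
})

test_that("fit metrics match hand arithmetic", {
  perfect <- evaluate_fit(c(1, 0.5, 0.2), c(1, 0.5, 0.2))
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$r2, 1)

  null_model <- evaluate_fit(c(1, 0.5, 0), rep(0.5, 3))
  expect_equal(null_model$r2, 0)

  m <- evaluate_fit(c(1, 0.5, 0), c(0.9, 0.5, 0.1))
  expect_equal(m$mse, 0.02 / 3)
  expect_equal(m$r2, 1 - 0.02 / 0.5)

  expect_warning(z <- evaluate_fit(c(1, 1, 1), c(1, 0.9, 1)), "variance")
  expect_true(is.na(z$r2))
})

test_that("noiseless Page data is recovered to high relative accuracy", {
  s <- page_series(k = 0.05, n = 1.2)
  fit <- fit_thin_layer_model(s, "page")
  expect_true(fit$converged)
  expect_equal(unname(fit$params["k"]), 0.05, tolerance = 1e-6)
  expect_equal(unname(fit$params["n"]), 1.2, tolerance = 1e-6)

  # Newton is Page with n = 1: strictly worse on n != 1 data
  newton <- fit_thin_layer_model(s, "newton")
  expect_gt(newton$mse, fit$mse)
})

test_that("quadratic data yields the exact Wang-Singh coefficients", {
  t <- seq(0, 100, by = 5)
  s <- moisture_series(t, 1 - 0.01 * t + 0.00002 * t^2)
  fit <- fit_thin_layer_model(s, "wang_singh")
  # normal-equation oracle for the same quadratic regression
  X <- cbind(t, t^2)
  beta <- solve(crossprod(X), crossprod(X, s$mr - 1))
  expect_equal(unname(fit$params["a"]), beta[1], tolerance = 1e-8)
  expect_equal(unname(fit$params["b"]), beta[2], tolerance = 1e-8)
  expect_equal(unname(fit$params["a"]), -0.01, tolerance = 1e-8)
})

test_that("nested models never beat their generalization in SSE", {
  cfg <- synthetic_config(noise_sd_mr = 0.015)
  for (i in 1:10) {
    run <- generate_drying_run(c(50, 70, 90)[(i %% 3) + 1], cfg, seed = 100 + i)
    s <- moisture_ratio(run)
    sse <- vapply(c("newton", "page", "henderson_pabis", "two_term"),
                  function(m) fit_thin_layer_model(s, m)$sse, 0)
    tol <- 1e-8 + 1e-6 * sse[["newton"]]
    expect_lte(sse[["page"]], sse[["newton"]] + tol)
    expect_lte(sse[["henderson_pabis"]], sse[["newton"]] + tol)
    expect_lte(sse[["two_term"]], sse[["henderson_pabis"]] + tol)
  }
})

test_that("fitted Page rate is positive and predictions stay in [0, 1]", {
  cfg <- synthetic_config(noise_sd_mr = 0.01)
  run <- generate_drying_run(70, cfg, seed = 21)
  s <- moisture_ratio(run)
  fit <- fit_thin_layer_model(s, "page")
  expect_gt(unname(fit$params["k"]), 0)
  pred <- predict(fit, s$time_min)
  expect_true(all(pred >= 0 & pred <= 1))
})

test_that("model ranking orders by r2, then mse, then parsimony", {
  page <- manual_fit("page", c(k = 0.02, n = 1.2), r2 = 0.999, mse = 0.001)
  newton <- manual_fit("newton", c(k = 0.02), r2 = 0.97, mse = 0.01)
  expect_identical(rank_models(list(page))[[1]]$model_name, "page")
  expect_identical(rank_models(list(newton, page))[[1]]$model_name, "page")

  # equal r2 and mse: fewer parameters first
  hp <- manual_fit("henderson_pabis", c(a = 1, k = 0.02),
                   r2 = 0.99, mse = 0.001)
  lg <- manual_fit("logarithmic", c(a = 1, k = 0.02, c = 0),
                   r2 = 0.99, mse = 0.001)
  expect_identical(rank_models(list(lg, hp))[[1]]$model_name,
                   "henderson_pabis")

  # non-converged fits sink to the bottom regardless of r2
  bad <- manual_fit("page", c(k = 0.1, n = 1), r2 = 0.9999, mse = 1e-6,
                    converged = FALSE)
  ranked <- rank_models(list(bad, newton))
  expect_identical(ranked[[2]]$model_name, "page")

  expect_error(rank_models(list()), "no fits")
})

test_that("drying time to target matches the Page closed form", {
  fit <- manual_fit("page", c(k = 0.05, n = 1))
  expect_equal(drying_time_to_target(fit, 0.5), log(2) / 0.05,
               tolerance = 1e-6)
  expect_equal(drying_time_to_target(fit, 1), 0)

  fit2 <- manual_fit("page", c(k = 0.02, n = 1.3))
  closed <- (-log(0.05) / 0.02)^(1 / 1.3)
  expect_equal(drying_time_to_target(fit2, 0.05), closed, tolerance = 1e-6)
})

test_that("an upward-turning quadratic that misses the target fails", {
  # vertex at t = 50 with MR = 0.75: never reaches 0.5
  fit <- manual_fit("wang_singh", c(a = -0.01, b = 1e-4))
  expect_error(drying_time_to_target(fit, 0.5), "never reaches")
  # but a reachable target is found
  expect_lt(drying_time_to_target(fit, 0.8), 50)
})
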