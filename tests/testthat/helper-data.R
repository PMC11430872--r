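# Noiseless Page-curve moisture series on a regular grid.
page_series <- function(k, n, times = seq(0, 150, by = 5), temp = 70) {
  moisture_series(times, exp(-k * times^n), temperature_C = temp,
                  run_id = sprintf("page_k%g_n%g", k, n))
}

# Small noiseless synthetic config for fast end-to-end checks.
quiet_config <- function(...) {
  synthetic_config(noise_sd_mr = 0, replicates = 1, ...)
}

# Hand-built model-fit object, for ranking/prediction tests that need
# exact coefficients rather than an optimizer output.
manual_fit <- function(model_name, params, r2 = 0.99, mse = 1e-4,
                       converged = TRUE) {
  structure(
    list(model_name = model_name, params = params, r2 = r2, mse = mse,
         sse = mse, converged = converged, n_obs = 10L,
         run_id = "manual", temperature_C = NA_real_),
    class = "rw_model_fit"
  )
}
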