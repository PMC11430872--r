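#' A single drying run (time/mass series)
#'
#' Container for one temperature x replicate drying record: sampling
#' times, wet masses, and the bone-dry mass used to convert masses to
#' dry-basis moisture.
#'
#' @param run_id Identifier.
#' @param temperature_C Water temperature (degrees C).
#' @param time_min Strictly increasing sampling times starting at 0 (min).
#' @param mass_g Sample masses (g), same length as `time_min`.
#' @param bone_dry_mass_g Bone-dry mass (g), positive.
#' @param equilibrium_moisture_db Equilibrium dry-basis moisture Me
#'   (fraction).  Defaults to 0: thin leaves dry to near-bone-dry and no
#'   equilibrium isotherm is modeled.
#' @return Object of class `rw_drying_run`.
#' @export
drying_run <- function(run_id, temperature_C, time_min, mass_g,
                       bone_dry_mass_g, equilibrium_moisture_db = 0) {
  if (length(time_min) != length(mass_g))
    stopf("time_min and mass_g must have equal length")
  if (length(time_min) < 2 || time_min[1] != 0 || any(diff(time_min) <= 0))
    stopf("time_min must be strictly increasing and start at 0")
  if (bone_dry_mass_g <= 0) stopf("bone_dry_mass_g must be > 0")
  if (any(mass_g < bone_dry_mass_g - 1e-9))
    stopf("masses below bone-dry mass")
  structure(
    list(run_id = as.character(run_id), temperature_C = temperature_C,
         time_min = as.numeric(time_min), mass_g = as.numeric(mass_g),
         bone_dry_mass_g = bone_dry_mass_g,
         equilibrium_moisture_db = equilibrium_moisture_db),
    class = "rw_drying_run"
  )
}

#' Moisture ratio of a drying run
#'
#' Converts masses to dry-basis moisture `X_t = (m_t - m_dry)/m_dry` and
#' normalizes against the initial and equilibrium moisture:
#' `MR_t = (X_t - Me)/(X_0 - Me)`.  The first value is exactly 1.
#'
#' @param run A [drying_run()].
#' @param clip Clamp the reported MR into `[0, 1]` (measurement noise can
#'   push raw values slightly outside).  Default `TRUE`.
#' @return Object of class `rw_moisture_series` with `time_min`, `mr`,
#'   `temperature_C`.
#' @export
moisture_ratio <- function(run, clip = TRUE) {
  stopifnot(inherits(run, "rw_drying_run"))
  X <- (run$mass_g - run$bone_dry_mass_g) / run$bone_dry_mass_g
  Me <- run$equilibrium_moisture_db
  if (X[1] <= Me)
    stopf("initial dry-basis moisture (%.4g) must exceed Me (%.4g)", X[1], Me)
  mr <- (X - Me) / (X[1] - Me)
  mr[1] <- 1
  if (clip) mr <- pmin(1, pmax(0, mr))
  structure(
    list(time_min = run$time_min, mr = mr,
         temperature_C = run$temperature_C, run_id = run$run_id),
    class = "rw_moisture_series"
  )
}

#' Construct a moisture series directly
#'
#' @param time_min Sampling times (min), starting at 0.
#' @param mr Moisture ratios; `mr[1]` must be 1.
#' @param temperature_C Temperature label (degrees C).
#' @param run_id Optional identifier.
#' @return Object of class `rw_moisture_series`.
#' @export
moisture_series <- function(time_min, mr, temperature_C = NA_real_,
                            run_id = NA_character_) {
  if (length(time_min) != length(mr)) stopf("unequal lengths")
  if (abs(mr[1] - 1) > 1e-12) stopf("mr[1] must be 1")
  structure(list(time_min = as.numeric(time_min), mr = as.numeric(mr),
                 temperature_C = temperature_C, run_id = run_id),
            class = "rw_moisture_series")
}

# --- thin-layer model registry ------------------------------------------

# Each entry: parameter names, MR(t; p), box bounds, and a start builder
# taking the Newton-rate log-linearization k0 as anchor.
.thin_layer_models <- list(
  newton = list(
    params = "k",
    fn = function(t, p) exp(-p[["k"]] * t),
    lower = c(k = 1e-8), upper = c(k = 10),
    start = function(k0) c(k = k0)
  ),
  page = list(
    params = c("k", "n"),
    fn = function(t, p) exp(-p[["k"]] * t^p[["n"]]),
    lower = c(k = 1e-8, n = 1e-3), upper = c(k = 10, n = 5),
    start = function(k0) c(k = k0, n = 1)
  ),
  henderson_pabis = list(
    params = c("a", "k"),
    fn = function(t, p) p[["a"]] * exp(-p[["k"]] * t),
    lower = c(a = -5, k = 1e-8), upper = c(a = 5, k = 10),
    start = function(k0) c(a = 1, k = k0)
  ),
  logarithmic = list(
    params = c("a", "k", "c"),
    fn = function(t, p) p[["a"]] * exp(-p[["k"]] * t) + p[["c"]],
    lower = c(a = -5, k = 1e-8, c = -5), upper = c(a = 5, k = 10, c = 5),
    start = function(k0) c(a = 1, k = k0, c = 0)
  ),
  wang_singh = list(
    params = c("a", "b"),
    fn = function(t, p) 1 + p[["a"]] * t + p[["b"]] * t^2,
    lower = c(a = -5, b = -5), upper = c(a = 5, b = 5),
    start = function(k0) c(a = -k0, b = 0)
  ),
  two_term = list(
    params = c("a", "k", "c", "k0"),
    fn = function(t, p)
      p[["a"]] * exp(-p[["k"]] * t) + p[["c"]] * exp(-p[["k0"]] * t),
    lower = c(a = -5, k = 1e-8, c = -5, k0 = 1e-8),
    upper = c(a = 5, k = 10, c = 5, k0 = 10),
    start = function(k0) c(a = 0.5, k = k0, c = 0.5, k0 = k0 * 2)
  )
)

#' Names of the supported thin-layer drying models
#' @return Character vector.
#' @export
thin_layer_models <- function() names(.thin_layer_models)

# Newton-rate anchor from a log-linearization of MR ~ exp(-k t);
# non-positive MR values are excluded here but retained in the SSE.
.newton_rate_guess <- function(time_min, mr) {
  ok <- mr > 0 & time_min >= 0
  if (sum(ok) < 2) return(0.01)
  sl <- unname(coef(lm(log(mr[ok]) ~ time_min[ok]))[2])
  if (!is.finite(sl) || sl >= 0) 0.01 else -sl
}

#' Fit a thin-layer drying model by nonlinear least squares
#'
#' Minimizes the sum of squared moisture-ratio residuals with the
#' Levenberg--Marquardt algorithm ([minpack.lm::nls.lm()]) under box
#' bounds (`k`, `k0` in (0, 10], `n` in (0, 5], `a`, `b`, `c` in
#' `[-5, 5]`), using a multi-start protocol: a deterministic start from
#' the Newton-model log-linearization plus seeded jittered restarts.  The
#' best converged start by SSE wins; if no start converges the best
#' attempt is returned with `converged = FALSE`.
#'
#' @param series An `rw_moisture_series`.
#' @param model_name One of [thin_layer_models()].
#' @param init Optional named start values overriding the default start.
#' @param bounds Optional list with `lower`/`upper` named vectors.
#' @param n_starts Number of starts (>= 1); default 5.
#' @return Object of class `rw_model_fit` with `model_name`, `params`,
#'   `r2`, `mse`, `sse`, `converged`, `n_obs`.
#' @export
fit_thin_layer_model <- function(series, model_name, init = NULL,
                                 bounds = NULL, n_starts = 5) {
  stopifnot(inherits(series, "rw_moisture_series"))
  model_name <- match.arg(model_name, thin_layer_models())
  spec <- .thin_layer_models[[model_name]]
  t <- series$time_min; y <- series$mr
  n_par <- length(spec$params)
  if (length(y) < max(4, n_par + 2))
    stopf("need at least %d observations for %s", max(4, n_par + 2),
          model_name)

  lower <- bounds$lower %||% spec$lower
  upper <- bounds$upper %||% spec$upper
  base_start <- spec$start(.newton_rate_guess(t, y))
  if (!is.null(init)) base_start[names(init)] <- init
  base_start <- pmin(pmax(base_start, lower), upper)

  resid_fn <- function(p) {
    names(p) <- spec$params
    spec$fn(t, p) - y
  }

  starts <- list(base_start)
  if (n_starts > 1) {
    jit <- with_seed(derive_seed(10007L, stage_tag(model_name), length(y)), {
      lapply(seq_len(n_starts - 1), function(i) {
        s <- base_start * exp(rnorm(n_par, 0, 0.5))
        s[base_start == 0] <- rnorm(sum(base_start == 0), 0, 0.1)
        pmin(pmax(s, lower), upper)
      })
    })
    starts <- c(starts, jit)
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = s, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-10, ptol = 1e-12
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:4
    if (is.null(best) || (conv && !best$conv) ||
        (conv == best$conv && sse < best$sse)) {
      best <- list(par = fit$par, sse = sse, conv = conv)
    }
  }
  if (is.null(best))
    stopf("all optimizer starts failed for model %s", model_name)

  p <- best$par; names(p) <- spec$params
  pred <- spec$fn(t, p)
  met <- evaluate_fit(y, pred)
  structure(
    list(model_name = model_name, params = p, r2 = met$r2, mse = met$mse,
         sse = best$sse, converged = best$conv, n_obs = length(y),
         run_id = series$run_id, temperature_C = series$temperature_C),
    class = "rw_model_fit"
  )
}

#' Predict moisture ratio from a fitted thin-layer model
#'
#' @param object An `rw_model_fit`.
#' @param time_min Times (min) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Numeric vector of predicted moisture ratios.
#' @export
predict.rw_model_fit <- function(object, time_min, ...) {
  spec <- .thin_layer_models[[object$model_name]]
  spec$fn(time_min, object$params)
}

#' @export
print.rw_model_fit <- function(x, ...) {
  cat(sprintf("<rw_model_fit> %s: %s | r2 = %.5f, mse = %.3g%s\n",
              x$model_name,
              paste(sprintf("%s = %.5g", names(x$params), x$params),
                    collapse = ", "),
              x$r2, x$mse,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Goodness-of-fit metrics for predicted vs observed moisture ratios
#'
#' `mse = mean((pre - exp)^2)`; `r2 = 1 - SS_res/SS_tot`, the standard
#' coefficient of determination.
#'
#' @param mr_exp Observed values.
#' @param mr_pre Predicted values, same length (>= 2).
#' @return List with `r2` and `mse`.  `r2` is `NA` (with a warning) when
#'   the observations have zero variance.
#' @export
evaluate_fit <- function(mr_exp, mr_pre) {
  if (length(mr_exp) != length(mr_pre)) stopf("unequal lengths")
  if (length(mr_exp) < 2) stopf("need at least 2 points")
  ss_res <- sum((mr_exp - mr_pre)^2)
  ss_tot <- sum((mr_exp - mean(mr_exp))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero variance in observations; r2 undefined", call. = FALSE)
    NA_real_
  } else 1 - ss_res / ss_tot
  list(r2 = r2, mse = ss_res / length(mr_exp))
}

#' Rank thin-layer model fits
#'
#' Converged fits first, then descending r2, ties broken by ascending
#' MSE, then by fewer parameters.
#'
#' @param fits List of `rw_model_fit` objects (>= 1).
#' @return The same list, reordered.
#' @export
rank_models <- function(fits) {
  if (!length(fits)) stopf("no fits to rank")
  stopifnot(all(vapply(fits, inherits, TRUE, "rw_model_fit")))
  conv <- vapply(fits, `[[`, TRUE, "converged")
  r2 <- vapply(fits, `[[`, 0, "r2")
  mse <- vapply(fits, `[[`, 0, "mse")
  np <- vapply(fits, function(f) length(f$params), 0L)
  fits[order(!conv, -r2, mse, np)]
}

#' Summarize a list of model fits as a data frame
#'
#' One row per fit with run, model, coefficients, r2 and MSE, matching
#' the layout of per-temperature fit-statistics tables.
#'
#' @param fits List of `rw_model_fit` objects.
#' @return data.frame.
#' @export
fit_table <- function(fits) {
  all_par <- unique(unlist(lapply(fits, function(f) names(f$params))))
  rows <- lapply(fits, function(f) {
    p <- setNames(rep(NA_real_, length(all_par)), all_par)
    p[names(f$params)] <- f$params
    data.frame(run_id = f$run_id %||% NA_character_,
               temperature_C = f$temperature_C %||% NA_real_,
               model = f$model_name, as.list(p), r2 = f$r2, mse = f$mse,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Time for a fitted model to reach a target moisture ratio
#'
#' Smallest `t >= 0` with `MR(t) <= mr_target`, found by geometric
#' bracketing of the first crossing followed by bisection
#' ([stats::uniroot()]) on the fitted curve.  For the Page model this
#' agrees with the closed form `t = (-log(mr_target)/k)^(1/n)`.
#'
#' @param fit A converged `rw_model_fit`.
#' @param mr_target Target moisture ratio in (0, 1).
#' @return Time in minutes.
#' @export
drying_time_to_target <- function(fit, mr_target) {
  stopifnot(inherits(fit, "rw_model_fit"))
  if (!fit$converged) stopf("fit did not converge")
  if (mr_target <= 0 || mr_target > 1) stopf("mr_target must be in (0, 1]")
  f <- function(t) predict(fit, t) - mr_target
  if (f(0) <= 0) return(0)
  lo <- 0; hi <- 1
  repeat {
    # scan inside (lo, hi] so non-monotone curves (e.g. an upward-turning
    # quadratic) cannot dip below the target unnoticed between endpoints
    grid <- seq(lo, hi, length.out = 65)[-1]
    below <- which(f(grid) <= 0)
    if (length(below)) {
      lo <- if (below[1] == 1) lo else grid[below[1] - 1]
      hi <- grid[below[1]]
      break
    }
    lo <- hi; hi <- hi * 2
    if (hi > 1e7)
      stopf("model %s never reaches MR = %g", fit$model_name, mr_target)
  }
  uniroot(f, c(lo, hi), tol = 1e-9)$root
}
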