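#' CIELAB color difference from a reference reading
#'
#' Euclidean distance in L*a*b* space:
#' `sqrt((L0-L)^2 + (a0-a)^2 + (b0-b)^2)`.  Symmetric in its arguments.
#'
#' @param fresh,dried Numeric length-3 vectors `(L*, a*, b*)`.
#' @return Non-negative color difference.
#' @export
delta_e <- function(fresh, dried) {
  fresh <- as.numeric(fresh); dried <- as.numeric(dried)
  if (length(fresh) != 3 || length(dried) != 3)
    stopf("color readings must be (L*, a*, b*) triples")
  sqrt(sum((fresh - dried)^2))
}

#' CIELAB chroma
#'
#' Radial saturation `sqrt(a*^2 + b*^2)`; invariant to the signs of a*
#' and b*.
#'
#' @param a_star,b_star Color coordinates; vectorized.
#' @return Chroma, non-negative.
#' @export
chroma <- function(a_star, b_star) sqrt(a_star^2 + b_star^2)

#' Rehydration ratio
#'
#' Rehydrated mass over dried mass after soaking; tracked per soak time
#' to form the three-phase uptake curve (fast rise, slowdown, plateau).
#'
#' @param rehydrated_mass_g Mass after soaking (g).
#' @param dried_mass_g Dried mass before soaking (g), positive.
#' @return Dimensionless ratio.
#' @export
rehydration_ratio <- function(rehydrated_mass_g, dried_mass_g) {
  if (any(dried_mass_g <= 0)) stopf("dried mass must be > 0")
  rehydrated_mass_g / dried_mass_g
}

#' DPPH antioxidant activity
#'
#' Percent reduction of DPPH-radical absorbance by the extract:
#' `100 (1 - A_sample/A_control)`.  Values below 0 (sample absorbs more
#' than the control) are reported as-is with a warning, never clipped
#' silently.
#'
#' @param a_sample Sample absorbance (>= 0).
#' @param a_control Control absorbance (> 0).
#' @return Antioxidant activity (%).
#' @export
antioxidant_pct <- function(a_sample, a_control) {
  if (any(a_control <= 0)) stopf("control absorbance must be > 0")
  if (any(a_sample < 0)) stopf("sample absorbance must be >= 0")
  if (any(a_sample > a_control))
    warning("sample absorbance exceeds control; negative activity reported",
            call. = FALSE)
  100 * (1 - a_sample / a_control)
}

#' Summarize a replicate quality panel
#'
#' Per-group mean and SD for every numeric column, plus percent-change
#' columns of the group means against a chosen reference group.
#'
#' @param records data.frame with a `label` column (temperature or
#'   `"fresh"`) and numeric metric columns; at least one row per group.
#' @param reference Optional label whose means serve as the
#'   percent-change reference.
#' @return data.frame: one row per label with `<metric>_mean`,
#'   `<metric>_sd` and, when `reference` is given, `<metric>_pct_change`.
#' @export
summarize_panel <- function(records, reference = NULL) {
  if (!nrow(records)) stopf("empty panel")
  if (!"label" %in% names(records)) stopf("records need a 'label' column")
  metrics <- names(records)[vapply(records, is.numeric, TRUE)]
  metrics <- setdiff(metrics, "replicate")
  if (!length(metrics)) stopf("no numeric metric columns")
  labs <- unique(records$label)
  out <- data.frame(label = labs, stringsAsFactors = FALSE)
  for (m in metrics) {
    mu <- vapply(labs, function(l)
      mean(records[[m]][records$label == l], na.rm = TRUE), 0)
    s <- vapply(labs, function(l) {
      v <- records[[m]][records$label == l]
      if (sum(!is.na(v)) < 2) 0 else sd(v, na.rm = TRUE)
    }, 0)
    out[[paste0(m, "_mean")]] <- mu
    out[[paste0(m, "_sd")]] <- s
  }
  if (!is.null(reference)) {
    if (!reference %in% labs) stopf("reference label '%s' absent", reference)
    for (m in metrics) {
      ref <- out[[paste0(m, "_mean")]][out$label == reference]
      out[[paste0(m, "_pct_change")]] <-
        if (is.na(ref) || ref == 0) NA_real_ else
          percent_change(ref, out[[paste0(m, "_mean")]])
    }
  }
  out
}
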