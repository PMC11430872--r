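#' Published reference summary tables for mint refractance-window drying
#'
#' The package ships the printed per-temperature summary tables of a mint
#' (*Mentha spicata*) refractance window drying study at water temperatures
#' of 50--90 degrees C, as plain-CSV fixtures.  They serve as inputs for the
#' parts of the chain that operate on summary statistics (Arrhenius
#' regression over reported diffusivities, thermodynamic identities, color
#' metrics, percent-change headlines); raw time series were not published.
#'
#' Available tables:
#' \describe{
#'   \item{`drying`}{per-temperature drying time (min), effective
#'     diffusivity (m^2/s), SEC (kWh/kg water), CO2 and NOx intensities
#'     (kg/kg water), each with its reported SD.}
#'   \item{`thermo`}{per-temperature enthalpy (kJ/mol), entropy
#'     (kJ/(mol K)) and Gibbs free energy (kJ/mol).}
#'   \item{`color`}{CIELAB L*, a*, b* with the reported Delta-E and chroma
#'     for the fresh reference and the five dried samples.}
#'   \item{`quality`}{rehydration ratio, total phenolics (mg GAE/100 g dw),
#'     total flavonoids (mg QE/100 g dw), DPPH antioxidant activity (%)
#'     and essential-oil yield (%).}
#' }
#'
#' @param table One of `"drying"`, `"thermo"`, `"color"`, `"quality"`.
#' @return A data.frame with one row per temperature (plus a fresh row for
#'   the color and quality panels).
#' @examples
#' ref_summary("drying")$deff_m2_s
#' @export
ref_summary <- function(table = c("drying", "thermo", "color", "quality")) {
  table <- match.arg(table)
  file <- system.file(
    "extdata",
    sprintf("reference_%s_summary.csv", table),
    package = "rwdry", mustWork = TRUE
  )
  read.csv(file, stringsAsFactors = FALSE)
}
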