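#' Activation enthalpy of drying
#'
#' Transition-state enthalpy `dH = Ea - R T` with T in kelvin, reported
#' in kJ/mol.
#'
#' @param Ea_J_per_mol Activation energy (J/mol), positive.
#' @param temperature_C Temperature (degrees C); vectorized.
#' @param constants See [physical_constants()].
#' @return Enthalpy in kJ/mol.
#' @export
enthalpy <- function(Ea_J_per_mol, temperature_C,
                     constants = physical_constants()) {
  if (any(Ea_J_per_mol <= 0)) stopf("Ea must be > 0")
  (Ea_J_per_mol - constants$R_J_per_molK * (temperature_C + 273.15)) / 1000
}

#' Activation entropy of drying
#'
#' Transition-state entropy from the Arrhenius pre-exponential factor:
#' `dS = R * (ln D0 - ln(kB/h) - ln T)` with `kB/h` the
#' Boltzmann-over-Planck frequency factor and T in kelvin; reported in
#' kJ/(mol K).  Strictly decreasing in temperature at fixed `D0`.
#'
#' @param D0_m2_s Pre-exponential factor (m^2/s), positive.
#' @param temperature_C Temperature (degrees C); vectorized.
#' @param constants See [physical_constants()].
#' @return Entropy in kJ/(mol K).
#' @export
entropy <- function(D0_m2_s, temperature_C,
                    constants = physical_constants()) {
  if (any(D0_m2_s <= 0)) stopf("D0 must be > 0")
  kb_over_h <- constants$boltzmann_J_per_K / constants$planck_J_s
  constants$R_J_per_molK *
    (log(D0_m2_s) - log(kb_over_h) - log(temperature_C + 273.15)) / 1000
}

#' Gibbs free energy of drying
#'
#' `dG = dH - T dS` with T in kelvin; all quantities in kJ-based units.
#'
#' @param dH_kJ_per_mol Enthalpy (kJ/mol).
#' @param dS_kJ_per_molK Entropy (kJ/(mol K)).
#' @param temperature_C Temperature (degrees C); vectorized.
#' @return Gibbs free energy in kJ/mol.
#' @export
gibbs <- function(dH_kJ_per_mol, dS_kJ_per_molK, temperature_C) {
  dH_kJ_per_mol - (temperature_C + 273.15) * dS_kJ_per_molK
}

#' Per-temperature thermodynamic summary
#'
#' Computes enthalpy, entropy and Gibbs free energy at each observed
#' temperature from an Arrhenius fit.  The Gibbs column satisfies
#' `dG = dH - T dS` exactly, by construction.
#'
#' @param arrhenius An `rw_arrhenius` object (see [arrhenius_fit()]).
#' @param temperature_C Temperatures at which to evaluate (degrees C).
#' @param constants See [physical_constants()].
#' @return data.frame with columns `temperature_C`, `dH_kJ_per_mol`,
#'   `dS_kJ_per_molK`, `dG_kJ_per_mol`.
#' @export
thermo_table <- function(arrhenius, temperature_C,
                         constants = physical_constants()) {
  stopifnot(inherits(arrhenius, "rw_arrhenius"))
  dH <- enthalpy(arrhenius$Ea_J_per_mol, temperature_C, constants)
  dS <- entropy(arrhenius$D0_m2_s, temperature_C, constants)
  data.frame(temperature_C = temperature_C, dH_kJ_per_mol = dH,
             dS_kJ_per_molK = dS,
             dG_kJ_per_mol = gibbs(dH, dS, temperature_C))
}
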