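#' Physical and spectroscopic constants
#'
#' Defaults used throughout the blood-flow quantification chain. All are
#' plain numbers so that every stage can be re-run with explicit overrides.
#'
#' @format A named list:
#' \describe{
#'   \item{c_vacuum}{Speed of light in vacuum, cm/ns.}
#'   \item{n_tissue}{Default tissue refractive index (dimensionless).}
#'   \item{eps_icg}{Decadic extinction coefficient of plasma-bound ICG at
#'     805 nm, per-uM per-cm. Configurable in every function that uses it;
#'     always recorded in outputs.}
#'   \item{ink_absorption_ratio}{Ratio of the ink absorption coefficient to
#'     its extinction coefficient measured in transmission (accounts for the
#'     scattering component of India-ink attenuation).}
#'   \item{rho_tissue}{Tissue density, g/mL, used to bridge mL/min/100 g
#'     blood flow to the per-second rate constant of the residue function.}
#'   \item{icg_molar_mass}{ICG molar mass, g/mol, for mg/L to uM conversion.}
#' }
#' @export
nirs_constants <- list(
  c_vacuum = 29.9792458,
  n_tissue = 1.4,
  eps_icg = 0.186,
  ink_absorption_ratio = 0.885,
  rho_tissue = 1.05,
  icg_molar_mass = 774.96
)

#' Convert an ICG mass concentration to molar units
#'
#' Dye-densitometer arterial curves are commonly reported in mg/L; the
#' deconvolution works in uM.
#'
#' @param mg_per_l Concentration in mg/L.
#' @param molar_mass ICG molar mass in g/mol.
#' @return Concentration in uM.
#' @export
icg_mg_per_l_to_um <- function(mg_per_l, molar_mass = nirs_constants$icg_molar_mass) {
  mg_per_l / molar_mass * 1000
}
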