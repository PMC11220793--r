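# Concentration conversions, supersaturation and thermodynamic driving force.

#' Describe the solute under study
#'
#' Bundles the two solute properties the nucleation analysis needs: the molar
#' mass (for concentration-unit conversions) and the molecular volume `v`
#' (for the thermodynamic parameter, the critical radius and the critical
#' cluster size). Defaults describe ritonavir; `molecular_volume_A3` defaults
#' to 903 A^3, the value implied by published critical-radius /
#' cluster-size pairs through v = (4*pi/3) r^3 / n.
#'
#' @param name Solute name.
#' @param molar_mass_g_mol Molar mass in g mol^-1; must be positive.
#' @param molecular_volume_A3 Molecular volume in cubic angstrom; must be
#'   positive.
#' @return A list of class `"solute_spec"`.
#' @examples
#' solute_spec()  # ritonavir defaults
#' @export
solute_spec <- function(name = "ritonavir",
                        molar_mass_g_mol = 720.94,
                        molecular_volume_A3 = 903) {
  if (!is.numeric(molar_mass_g_mol) || molar_mass_g_mol <= 0)
    stop_domain("molar_mass_g_mol must be > 0 (got %s)", molar_mass_g_mol)
  if (!is.numeric(molecular_volume_A3) || molecular_volume_A3 <= 0)
    stop_domain("molecular_volume_A3 must be > 0 (got %s)", molecular_volume_A3)
  structure(list(name = name,
                 molar_mass_g_mol = molar_mass_g_mol,
                 molecular_volume_A3 = molecular_volume_A3),
            class = "solute_spec")
}

#' Convert a mole-fraction concentration to a solvent mass ratio
#'
#' For a binary solution with solute mole fraction `x`, the mass of solute
#' per unit mass of solvent is `x * M_solute / ((1 - x) * M_solvent)`.
#' This reconciles solubility tables reported in mole fraction with
#' supersaturated concentrations reported in g of solute per g of solvent.
#'
#' @param x Solute mole fraction, in `[0, 1)`. Vectorised.
#' @param solute_mm,solvent_mm Molar masses in g mol^-1.
#' @return Concentration in g solute per g solvent.
#' @seealso [mass_ratio_to_mole_fraction()] for the inverse.
#' @examples
#' mole_fraction_to_mass_ratio(1.33e-3, 720.94, 88.11)  # ethyl acetate
#' @export
mole_fraction_to_mass_ratio <- function(x, solute_mm, solvent_mm) {
  if (any(!is.finite(x)) || any(x < 0) || any(x >= 1))
    stop_domain("mole fraction must lie in [0, 1)")
  if (any(solute_mm <= 0) || any(solvent_mm <= 0))
    stop_domain("molar masses must be > 0")
  x * solute_mm / ((1 - x) * solvent_mm)
}

#' @rdname mole_fraction_to_mass_ratio
#' @param c Concentration in g solute per g solvent (for the inverse
#'   direction). Vectorised.
#' @export
mass_ratio_to_mole_fraction <- function(c, solute_mm, solvent_mm) {
  if (any(!is.finite(c)) || any(c < 0))
    stop_domain("mass ratio must be >= 0")
  if (any(solute_mm <= 0) || any(solvent_mm <= 0))
    stop_domain("molar masses must be > 0")
  n_ratio <- c * solvent_mm / solute_mm # moles solute per mole solvent
  n_ratio / (1 + n_ratio)
}

#' Supersaturation ratio
#'
#' The supersaturation S is the ratio of the solution concentration `c` to
#' the equilibrium solubility `c_star`, both as mass of solute per mass of
#' solvent. S > 1 means the solution is supersaturated and can nucleate.
#'
#' @param c Solution concentration, g/g; must be positive. Vectorised.
#' @param c_star Equilibrium solubility, g/g; must be positive.
#' @return Dimensionless supersaturation ratio.
#' @export
supersaturation <- function(c, c_star) {
  if (any(!is.finite(c)) || any(c <= 0))
    stop_domain("concentration must be > 0")
  if (any(!is.finite(c_star)) || any(c_star <= 0))
    stop_domain("solubility must be > 0")
  c / c_star
}

#' Thermodynamic driving force for nucleation
#'
#' The molar free-energy difference propelling crystallization,
#' `RT ln S`, with R = 8.314 J mol^-1 K^-1. Zero at saturation, negative for
#' undersaturated solutions.
#'
#' @param S Supersaturation ratio; must be positive. Vectorised.
#' @param T_K Absolute temperature in kelvin; must be positive.
#' @return Driving force in J mol^-1.
#' @examples
#' driving_force(4.20, 283.15)
#' @export
driving_force <- function(S, T_K) {
  if (any(!is.finite(S)) || any(S <= 0))
    stop_domain("supersaturation must be > 0")
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop_domain("temperature must be > 0 K")
  nk_constants$r_gas * T_K * log(S)
}

#' Assemble a supersaturated crystallization condition
#'
#' Combines solvent identity, temperature, concentration and (derived or
#' supplied) supersaturation into one validated record carrying the driving
#' force.
#'
#' @param solvent Solvent name.
#' @param T_K Temperature, kelvin.
#' @param c_g_per_g Solution concentration, g solute per g solvent.
#' @param c_star_g_per_g Equilibrium solubility, g/g; used to derive S when
#'   `S` is `NULL`.
#' @param S Supersaturation; derived from `c_g_per_g / c_star_g_per_g` when
#'   omitted.
#' @return A one-row data.frame with columns `solvent`, `T_K`, `c_g_per_g`,
#'   `S`, `driving_force_J_mol`.
#' @export
supersaturated_condition <- function(solvent, T_K, c_g_per_g,
                                     c_star_g_per_g = NULL, S = NULL) {
  if (is.null(S)) {
    if (is.null(c_star_g_per_g))
      stop_domain("either S or c_star_g_per_g must be supplied")
    S <- supersaturation(c_g_per_g, c_star_g_per_g)
  }
  if (S <= 0) stop_domain("supersaturation must be > 0")
  data.frame(solvent = solvent, T_K = T_K, c_g_per_g = c_g_per_g, S = S,
             driving_force_J_mol = driving_force(S, T_K),
             stringsAsFactors = FALSE)
}
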