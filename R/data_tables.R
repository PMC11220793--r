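# Published ritonavir form I nucleation data, transcribed as built-in
# worked inputs. All isothermal measurements at 283.15 K; concentrations
# are g solute per g solvent, solubilities mole fraction, rates m^-3 s^-1,
# radii angstrom, solvation free energies kcal mol^-1.

#' Published nucleation parameters for ritonavir form I at 283.15 K
#'
#' Per-condition table for crystallization of ritonavir form I from
#' acetone, ethyl acetate, acetonitrile and toluene: equilibrium
#' solubility (mole fraction), supersaturated concentration, reported
#' supersaturation ratio and driving force, estimated nucleation rate,
#' critical nucleus radius and molecule count, per-solvent fitted
#' `ln A0`, and MD-derived solvation free energy of the solute.
#'
#' The toluene supersaturations are reported values that are not the
#' quotient of the printed concentration and converted solubility (a
#' known internal inconsistency of the source data); they are stored
#' verbatim. See [check_supersaturation_consistency()].
#'
#' @return A data.frame with one row per (solvent, supersaturation)
#'   condition.
#' @export
ritonavir_nucleation_table <- function() {
  rows <- rbind(
    c(4.30, 224.42, 4.20, 3378.35,  58.17, 10.93,  6.06),
    c(4.30, 236.99, 4.44, 3509.16, 102.38, 10.53,  5.41),
    c(4.30, 253.54, 4.75, 3668.04, 187.15, 10.07,  4.73),
    c(4.30, 274.35, 5.14, 3853.80, 245.79,  9.59,  4.08),
    c(1.33,  52.24, 4.80, 3692.69,  64.27,  6.26,  1.13),
    c(1.33,  54.85, 5.04, 3807.55,  73.61,  6.07,  1.04),
    c(1.33,  57.79, 5.31, 3930.40,  89.43,  5.88,  0.94),
    c(0.66,  59.81, 5.16, 3862.94,  62.79, 14.20, 13.27),
    c(0.66,  64.56, 5.57, 4042.94, 250.29, 13.57, 11.57),
    c(0.66,  67.46, 5.82, 4146.29, 124.45, 13.23, 10.73),
    c(0.66,  70.71, 6.10, 4256.91, 659.70, 12.88,  9.91),
    c(0.22,  19.40, 13.11, 6058.01,  70.95,  7.32,  1.82),
    c(0.22,  20.76, 14.03, 6217.67,  99.32,  7.14,  1.68),
    c(0.22,  23.52, 15.89, 6510.74, 138.07,  6.81,  1.47))
  solvent <- rep(c("acetone", "ethyl acetate", "acetonitrile", "toluene"),
                 c(4, 3, 4, 3))
  ln_A0 <- rep(c(6.33, 2.58, 12.22, 2.18), c(4, 3, 4, 3))
  solvation <- rep(c(-37.48, -36.78, -33.98, -33.08), c(4, 3, 4, 3))
  data.frame(solvent = solvent, T_K = 283.15,
             x_star = rows[, 1] * 1e-3,
             c_g_per_g = rows[, 2] * 1e-3,
             S = rows[, 3],
             rt_ln_s_J_mol = rows[, 4],
             J = rows[, 5],
             r_c_A = rows[, 6],
             n_star = rows[, 7],
             ln_A0 = ln_A0,
             solvation_kcal_mol = solvation,
             stringsAsFactors = FALSE)
}

#' Published solvent properties and equal-induction-time driving forces
#'
#' Solvent-level table: molar mass, boiling point, viscosity, dipole
#' moment, dielectric constant, the driving force each solvent needs to
#' reach a common 13320 s induction time, the CNT interfacial energy, and
#' the MD solvation free energy (ethanol carries only the solvation
#' entry: nucleation there was too slow to measure).
#'
#' @return A data.frame with one row per solvent.
#' @export
ritonavir_solvent_properties <- function() {
  data.frame(
    solvent = c("acetone", "ethyl acetate", "acetonitrile", "toluene",
                "ethanol"),
    molar_mass_g_mol = c(58.08, 88.11, 41.05, 92.14, 46.07),
    equal_time_driving_force_J_mol = c(3437, 3806, 3900, 6079, NA),
    gamma_mJ_m2 = c(3.39, 2.12, 5.04, 4.08, NA),
    boiling_point_C = c(56.53, 77.00, 81.60, 110.63, NA),
    viscosity_mPa_s = c(0.33, 0.46, 0.38, 0.59, NA),
    dipole_moment_D = c(3.00, 1.60, 3.92, 0.36, NA),
    dielectric_constant = c(20.60, 6.02, 37.50, 2.38, NA),
    solvation_kcal_mol = c(-37.48, -36.78, -33.98, -33.08, -38.89),
    stringsAsFactors = FALSE)
}

#' Check supersaturation self-consistency of a condition table
#'
#' For each row, recomputes S as the quotient of the concentration and the
#' solubility converted from mole fraction, and reports the relative gap
#' to the stored S. Rows whose gap exceeds `tol` are flagged rather than
#' overwritten: stored supersaturations are treated as authoritative
#' reported values.
#'
#' @param tbl A data.frame with columns `solvent`, `x_star`, `c_g_per_g`,
#'   `S` (e.g. [ritonavir_nucleation_table()]).
#' @param solvents Solvent property table with `solvent` and
#'   `molar_mass_g_mol` columns.
#' @param solute A [solute_spec()].
#' @param tol Relative-gap threshold for flagging (default 1%).
#' @return `tbl` with added columns `S_recomputed`, `S_rel_gap`,
#'   `S_consistent`.
#' @export
check_supersaturation_consistency <- function(
    tbl, solvents = ritonavir_solvent_properties(),
    solute = solute_spec(), tol = 0.01) {
  mm <- solvents$molar_mass_g_mol[match(tbl$solvent, solvents$solvent)]
  if (any(is.na(mm)))
    stop_domain("unknown solvent(s): %s",
                paste(unique(tbl$solvent[is.na(mm)]), collapse = ", "))
  c_star <- mole_fraction_to_mass_ratio(tbl$x_star,
                                        solute$molar_mass_g_mol, mm)
  S_re <- supersaturation(tbl$c_g_per_g, c_star)
  gap <- abs(S_re - tbl$S) / tbl$S
  tbl$S_recomputed <- S_re
  tbl$S_rel_gap <- gap
  tbl$S_consistent <- gap <= tol
  tbl
}
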