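# Closed-form classical nucleation theory (CNT) quantities.
#
# Rate law:      J  = A0 * S * exp(-B / ln^2 S)
# Thermodynamic: B  = 16 pi gamma^3 v^2 / (3 k^3 T^3)
# Critical size: rc = 2 gamma v / (k T ln S)
# Cluster count: n* = (4 pi / 3) rc^3 / v  =  2 B / ln^3 S
# Zeldovich:     z  = ln^2 S / (2 sqrt(3 pi B))
# Attachment:    f*C0 = A0 * S / z
#
# gamma enters in mJ m^-2 and v in A^3 at the interface; internally SI.

#' Thermodynamic parameter B of classical nucleation theory
#'
#' `B = 16 pi gamma^3 v^2 / (3 k^3 T^3)`, the dimensionless barrier
#' parameter controlling how steeply the nucleation rate falls as the
#' supersaturation decreases. Cubic in the interfacial energy and quadratic
#' in the molecular volume.
#'
#' @param gamma_mJ_m2 Effective solid-liquid interfacial energy, mJ m^-2;
#'   must be non-negative. Vectorised.
#' @param v_A3 Molecular volume, cubic angstrom; must be positive.
#' @param T_K Temperature, kelvin; must be positive.
#' @return Dimensionless B >= 0.
#' @examples
#' thermodynamic_parameter(3.397, 902.6, 283.15)
#' @export
thermodynamic_parameter <- function(gamma_mJ_m2, v_A3, T_K) {
  if (any(gamma_mJ_m2 < 0)) stop_domain("gamma must be >= 0")
  if (any(v_A3 <= 0)) stop_domain("molecular volume must be > 0")
  if (any(T_K <= 0)) stop_domain("temperature must be > 0 K")
  g <- mJm2_to_Jm2(gamma_mJ_m2)
  v <- A3_to_m3(v_A3)
  k <- nk_constants$k_boltzmann
  16 * pi * g^3 * v^2 / (3 * k^3 * T_K^3)
}

#' Interfacial energy from the thermodynamic parameter
#'
#' Exact inverse of [thermodynamic_parameter()]:
#' `gamma = (3 B k^3 T^3 / (16 pi v^2))^(1/3)`.
#'
#' @param B Dimensionless thermodynamic parameter; must be >= 0. Vectorised.
#' @inheritParams thermodynamic_parameter
#' @return Interfacial energy in mJ m^-2.
#' @export
interfacial_energy_from_B <- function(B, v_A3, T_K) {
  if (any(B < 0)) stop_domain("B must be >= 0")
  if (any(v_A3 <= 0)) stop_domain("molecular volume must be > 0")
  if (any(T_K <= 0)) stop_domain("temperature must be > 0 K")
  v <- A3_to_m3(v_A3)
  k <- nk_constants$k_boltzmann
  Jm2_to_mJm2((3 * B * k^3 * T_K^3 / (16 * pi * v^2))^(1 / 3))
}

#' Critical nucleus radius
#'
#' `rc = 2 gamma v / (k T ln S)`: the cluster radius at the top of the
#' nucleation free-energy barrier. Clusters larger than `rc` tend to grow;
#' smaller ones tend to redissolve. Only defined above saturation (S > 1);
#' the product `rc * ln S` is independent of S at fixed gamma, v, T.
#'
#' @inheritParams thermodynamic_parameter
#' @param S Supersaturation ratio; must exceed 1. Vectorised.
#' @return Critical radius in angstrom.
#' @examples
#' critical_radius(3.39, 903, 283.15, S = 4.20)
#' @export
critical_radius <- function(gamma_mJ_m2, v_A3, T_K, S) {
  if (any(gamma_mJ_m2 <= 0)) stop_domain("gamma must be > 0")
  if (any(v_A3 <= 0)) stop_domain("molecular volume must be > 0")
  if (any(T_K <= 0)) stop_domain("temperature must be > 0 K")
  if (any(S <= 1))
    stop_domain("no finite critical nucleus at or below saturation (S <= 1)")
  g <- mJm2_to_Jm2(gamma_mJ_m2)
  v <- A3_to_m3(v_A3)
  k <- nk_constants$k_boltzmann
  m_to_A(2 * g * v / (k * T_K * log(S)))
}

#' Number of molecules in a critical cluster
#'
#' Geometric count `n* = (4 pi / 3) rc^3 / v`. Algebraically identical to
#' `2 B / ln^3 S` when `rc` comes from [critical_radius()] with the same
#' parameters.
#'
#' @param radius_A Cluster radius in angstrom; must be >= 0. Vectorised.
#' @param v_A3 Molecular volume, cubic angstrom; must be positive.
#' @return Dimensionless molecule count (not rounded).
#' @examples
#' critical_cluster_size(10.93, 902.6)
#' @export
critical_cluster_size <- function(radius_A, v_A3) {
  if (any(radius_A < 0)) stop_domain("radius must be >= 0")
  if (any(v_A3 <= 0)) stop_domain("molecular volume must be > 0")
  (4 * pi / 3) * radius_A^3 / v_A3
}

#' Steady-state nucleation rate
#'
#' The CNT rate law `J = A0 * S * exp(-B / ln^2 S)` in m^-3 s^-1, with the
#' pre-exponential supplied on the log scale as fitted from induction-time
#' data. Strictly increasing in S; reduces to `A0 * S` as B -> 0.
#'
#' @param ln_A0 Natural log of the pre-exponential kinetic factor,
#'   ln(m^-3 s^-1).
#' @param S Supersaturation ratio; must exceed 1. Vectorised.
#' @param B Dimensionless thermodynamic parameter; must be >= 0.
#' @return Nucleation rate in m^-3 s^-1.
#' @export
nucleation_rate <- function(ln_A0, S, B) {
  if (any(S <= 1)) stop_domain("rate law requires S > 1")
  if (any(B < 0)) stop_domain("B must be >= 0")
  exp(ln_A0) * S * exp(-B / log(S)^2)
}

#' Zeldovich factor and attachment frequency
#'
#' The Zeldovich factor `z = ln^2 S / (2 sqrt(3 pi B))` corrects the
#' equilibrium cluster population for the steady-state flux over the
#' barrier; the attachment rate `f * C0 = A0 * S / z` is the monomer
#' addition frequency to a critical cluster times the concentration of
#' nucleation sites.
#'
#' @inheritParams nucleation_rate
#' @return A data.frame with columns `zeldovich` (dimensionless) and
#'   `attachment_rate` (m^-3 s^-1), one row per supersaturation.
#' @examples
#' zeldovich_and_attachment(6.33, S = 4.20, B = 8.95)
#' @export
zeldovich_and_attachment <- function(ln_A0, S, B) {
  if (any(S <= 1)) stop_domain("requires S > 1")
  if (any(B <= 0)) stop_domain("B must be > 0")
  z <- log(S)^2 / (2 * sqrt(3 * pi * B))
  data.frame(zeldovich = z, attachment_rate = exp(ln_A0) * S / z)
}

#' Bundle CNT parameters with consistency checking
#'
#' Holds `(ln_A0, B, gamma, v, T)` together; when both `B` and `gamma` are
#' given they must agree through the barrier relation to 1e-9 relative,
#' otherwise the missing one is derived.
#'
#' @param ln_A0 Log pre-exponential factor, ln(m^-3 s^-1); may be `NA`.
#' @param B Dimensionless thermodynamic parameter (optional if `gamma_mJ_m2`
#'   given).
#' @param gamma_mJ_m2 Interfacial energy, mJ m^-2 (optional if `B` given).
#' @param v_A3 Molecular volume, cubic angstrom.
#' @param T_K Temperature, kelvin.
#' @return A list of class `"cnt_parameters"`.
#' @export
cnt_parameters <- function(ln_A0 = NA_real_, B = NULL, gamma_mJ_m2 = NULL,
                           v_A3, T_K) {
  if (is.null(B) && is.null(gamma_mJ_m2))
    stop_domain("supply at least one of B, gamma_mJ_m2")
  if (is.null(B)) B <- thermodynamic_parameter(gamma_mJ_m2, v_A3, T_K)
  if (is.null(gamma_mJ_m2)) {
    gamma_mJ_m2 <- interfacial_energy_from_B(B, v_A3, T_K)
  } else {
    B_check <- thermodynamic_parameter(gamma_mJ_m2, v_A3, T_K)
    if (B > 0 && abs(B_check - B) / B > 1e-9)
      stop_domain("B and gamma are mutually inconsistent (relative gap %.3g)",
                  abs(B_check - B) / max(B, .Machine$double.eps))
  }
  structure(list(ln_A0 = ln_A0, B = B, gamma_mJ_m2 = gamma_mJ_m2,
                 v_A3 = v_A3, T_K = T_K),
            class = "cnt_parameters")
}

#' Critical-cluster properties at one supersaturation
#'
#' Evaluates radius, molecule count, Zeldovich factor and attachment rate
#' for a parameter set at supersaturation `S`.
#'
#' @param params A `"cnt_parameters"` object.
#' @param S Supersaturation ratio (> 1). Vectorised.
#' @return A data.frame with columns `S`, `r_c_A`, `n_star`, `zeldovich`,
#'   `attachment_rate`.
#' @export
critical_cluster <- function(params, S) {
  stopifnot(inherits(params, "cnt_parameters"))
  r <- critical_radius(params$gamma_mJ_m2, params$v_A3, params$T_K, S)
  za <- zeldovich_and_attachment(params$ln_A0, S, params$B)
  data.frame(S = S, r_c_A = r,
             n_star = critical_cluster_size(r, params$v_A3),
             zeldovich = za$zeldovich,
             attachment_rate = za$attachment_rate)
}
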