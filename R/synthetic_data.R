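# Seeded generators that emulate the statistical structure the analysis
# assumes: exponential nucleation waiting times with detection lag and
# right-censoring, three-state circular dihedral mixtures coupled to a
# two-state hydrogen-bond process, and toy conformer geometries with
# controllable descriptors.

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Parameters for the synthetic-data generators
#'
#' Defaults mirror the experimental design the estimators are meant for:
#' 8 replicate 1 mL vials per supersaturation held isothermally for 20 h
#' (right-censoring any vial that has not nucleated), a supersaturation
#' grid like a single-solvent campaign, rate-law parameters of the
#' magnitude recovered from published ritonavir data (ln A0 = 8.2,
#' B = 11.3), and unimodal-per-state dihedral ensembles with an
#' intermediate-dominant class mix and high hydrogen-bond occupancy.
#'
#' @param seed Integer seed; every generator call is reproducible given
#'   the spec.
#' @param induction List: `ln_A0` (ln m^-3 s^-1), `B`, `vial_volume_m3`,
#'   `t_growth_s`, `hold_time_s`, `S_grid`, `n_replicates`, `T_K`.
#' @param conformers List: `populations` (cis/intermediate/trans, sums to
#'   1), `kappa` (von Mises concentrations per class), `imhb_prob` (per
#'   class), `n_frames`.
#' @param geometry List: `n_atoms` (>= 7), `bond_A` (bond length scale).
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(seed = 1L,
                           induction = list(),
                           conformers = list(),
                           geometry = list()) {
  ind <- utils::modifyList(list(
    ln_A0 = 8.2, B = 11.3, vial_volume_m3 = 1e-6, t_growth_s = 0,
    hold_time_s = 72000, S_grid = c(4.20, 4.44, 4.75, 5.14),
    n_replicates = 8L, T_K = 283.15), induction)
  conf <- utils::modifyList(list(
    populations = c(cis = 0.2, intermediate = 0.6, trans = 0.2),
    kappa = c(50, 50, 50),
    imhb_prob = c(0.90, 0.95, 0.85),
    n_frames = 10000L), conformers)
  geo <- utils::modifyList(list(n_atoms = 8L, bond_A = 1.5), geometry)
  bad <- character(0)
  if (abs(sum(conf$populations) - 1) > 1e-12 || any(conf$populations < 0))
    bad <- c(bad, "conformers$populations must be >= 0 and sum to 1")
  if (ind$n_replicates < 1) bad <- c(bad, "induction$n_replicates must be >= 1")
  if (ind$t_growth_s < 0 || ind$hold_time_s <= ind$t_growth_s)
    bad <- c(bad, "induction needs hold_time_s > t_growth_s >= 0")
  if (ind$vial_volume_m3 <= 0) bad <- c(bad, "induction$vial_volume_m3 must be > 0")
  if (any(ind$S_grid <= 1)) bad <- c(bad, "induction$S_grid must all exceed 1")
  if (geo$n_atoms < 4) bad <- c(bad, "geometry$n_atoms must be >= 4")
  if (length(bad))
    stop_domain("invalid synthetic spec: %s", paste(bad, collapse = "; "))
  structure(list(seed = as.integer(seed), induction = ind,
                 conformers = conf, geometry = geo),
            class = "synthetic_spec")
}

#' Generate replicate induction-time campaigns
#'
#' For each supersaturation on the grid the nucleation rate follows the
#' CNT rate law `J = A0 S exp(-B / ln^2 S)`; per-vial waiting times are
#' exponential with rate `J * V`, shifted by the detection/growth lag, and
#' right-censored at the hold time.
#'
#' @param spec A [synthetic_spec()].
#' @return A named list (one element per grid supersaturation) of
#'   [induction_replicates()] objects; names are the `S` values.
#' @export
gen_induction_times <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$induction
  with_seed(spec$seed, {
    out <- lapply(p$S_grid, function(S) {
      J <- nucleation_rate(p$ln_A0, S, p$B)
      wait <- stats::rexp(p$n_replicates, rate = J * p$vial_volume_m3)
      obs <- wait + p$t_growth_s
      cens <- obs > p$hold_time_s
      obs[cens] <- p$hold_time_s
      induction_replicates(obs, cens,
                           vial_volume_m3 = p$vial_volume_m3,
                           hold_time_s = p$hold_time_s,
                           condition = list(S = S, T_K = p$T_K, J_true = J))
    })
    names(out) <- format(p$S_grid)
    out
  })
}

# Best-Fisher (1979) rejection sampler for the von Mises distribution.
rvonmises <- function(n, mu_deg, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -180, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1
      out[i] <- sign(stats::runif(1) - 0.5) * acos(pmin(1, pmax(-1, f)))
    }
  }
  wrap_deg(out * 180 / pi + mu_deg)
}

#' Generate a synthetic dihedral / hydrogen-bond state series
#'
#' Frames are drawn from a stationary three-state process with the given
#' class populations; each frame's angle comes from a von Mises
#' distribution centred at 0 (cis), +-90 with equal lobe weight
#' (intermediate) or 180 (trans) with the class concentration, and the
#' hydrogen-bond flag is Bernoulli with the class-specific probability.
#' The reported `class` column is re-derived from the angle via
#' [classify_phenyl()], so rare cross-bin leakage at low concentration is
#' visible; the generating class is kept in the `generating_class` column.
#'
#' @param spec A [synthetic_spec()].
#' @return A data.frame of class `"conformer_series"` with columns
#'   `frame`, `angle_deg`, `class`, `imhb`, `generating_class`.
#' @export
gen_dihedral_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$conformers
  lev <- c("cis", "intermediate", "trans")
  with_seed(spec$seed + 1L, {
    n <- p$n_frames
    cls <- sample(3L, n, replace = TRUE, prob = p$populations)
    angle <- numeric(n)
    for (k in 1:3) {
      idx <- which(cls == k)
      if (!length(idx)) next
      mu <- switch(k, 0, NA, 180)
      if (k == 2) {
        lobe <- sample(c(-90, 90), length(idx), replace = TRUE)
        angle[idx] <- rvonmises(length(idx), 0, p$kappa[k]) + lobe
      } else {
        angle[idx] <- rvonmises(length(idx), mu, p$kappa[k])
      }
    }
    angle <- wrap_deg(angle)
    imhb <- stats::rbinom(n, 1L, p$imhb_prob[cls])
    out <- data.frame(frame = seq_len(n), angle_deg = angle,
                      class = classify_phenyl(angle), imhb = imhb,
                      generating_class = factor(lev[cls], levels = lev))
    class(out) <- c("conformer_series", class(out))
    out
  })
}

#' Generate a toy conformer trajectory with controllable descriptors
#'
#' Builds a jointed-chain geometry whose leading four atoms realise a
#' requested torsion exactly, plus a hydroxyl-like donor/hydrogen pair and
#' an acceptor placed at a requested H...acceptor distance and
#' donor-H...acceptor angle. Useful as a constructive fixture: the
#' descriptors measured on the frame reproduce the requested values.
#'
#' @param spec A [synthetic_spec()]; `geometry$n_atoms` sets the atom
#'   count (>= 7 to carry the hydrogen-bond triplet).
#' @param torsion_deg Requested torsion of atoms 1-4, degrees.
#' @param ha_dist_A Requested H...acceptor distance, angstrom.
#' @param dha_angle_deg Requested donor-H...acceptor angle, degrees.
#' @param n_frames Number of (identical) frames to emit.
#' @return A `"trajectory"` object with selections `phenyl_dihedral`,
#'   `imhb_donor`, `imhb_hydrogen`, `imhb_acceptor` (0-based).
#' @export
gen_toy_conformer <- function(spec, torsion_deg = 90, ha_dist_A = 1.8,
                              dha_angle_deg = 160, n_frames = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  g <- spec$geometry
  n <- max(g$n_atoms, 7L)
  b <- g$bond_A
  tau <- torsion_deg * pi / 180
  # chain: p2 at origin, central bond along z, outer bonds set the torsion
  p1 <- c(b, 0, 0)
  p2 <- c(0, 0, 0)
  p3 <- c(0, 0, b)
  p4 <- p3 + c(b * cos(tau), b * sin(tau), 0)
  # donor-H-acceptor triplet well away from the chain, D-H along z
  H <- c(6, 6, 0)
  D <- H + c(0, 0, 0.97)
  arad <- dha_angle_deg * pi / 180
  A <- H + ha_dist_A * c(sin(arad), 0, cos(arad))
  coords <- rbind(p1, p2, p3, p4, D, H, A)
  extra <- n - 7L
  if (extra > 0)
    coords <- rbind(coords, cbind(seq_len(extra) * b, -3, 0))
  rownames(coords) <- NULL
  names_vec <- c("C1", "C2", "C3", "C4", "O1", "H1", "O2",
                 if (extra > 0) paste0("C", 4L + seq_len(extra)))
  sel <- list(phenyl_dihedral = 0:3, imhb_donor = 4L,
              imhb_hydrogen = 5L, imhb_acceptor = 6L)
  trajectory(rep(list(coords), n_frames), names_vec, selections = sel)
}

#' Generate a noiseless CNT rate table with its derived quantities
#'
#' Evaluates the rate law on a supersaturation grid and attaches the
#' analytically expected interfacial energy, critical radius, cluster
#' size, Zeldovich factor and attachment rate per row, for use as an
#' oracle in round-trip tests of the fitting chain.
#'
#' @param spec A [synthetic_spec()]; uses the `induction` parameters and
#'   the default molecular volume of [solute_spec()].
#' @param v_A3 Molecular volume, cubic angstrom.
#' @return A data.frame with columns `S`, `J`, `gamma_mJ_m2`, `r_c_A`,
#'   `n_star`, `zeldovich`, `attachment_rate`.
#' @export
gen_rate_table <- function(spec, v_A3 = solute_spec()$molecular_volume_A3) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$induction
  S <- p$S_grid
  J <- nucleation_rate(p$ln_A0, S, p$B)
  gamma <- interfacial_energy_from_B(p$B, v_A3, p$T_K)
  r_c <- critical_radius(gamma, v_A3, p$T_K, S)
  za <- zeldovich_and_attachment(p$ln_A0, S, p$B)
  data.frame(S = S, J = J, gamma_mJ_m2 = gamma, r_c_A = r_c,
             n_star = critical_cluster_size(r_c, v_A3),
             zeldovich = za$zeldovich,
             attachment_rate = za$attachment_rate)
}
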