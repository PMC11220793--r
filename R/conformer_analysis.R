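# Per-frame conformational descriptors: signed dihedrals, three-state
# phenyl classification, geometric intramolecular H-bond detection, radius
# of gyration, and optimal-superposition RMSD.

#' Signed dihedral (torsion) angle of four points
#'
#' IUPAC-signed torsion of the p1-p2-p3-p4 arrangement, reported in
#' degrees on the half-open interval `[-180, 180)` (so the planar anti
#' arrangement is -180, not +180). Invariant under global rotation and
#' translation of all four points.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors, angstrom.
#' @return Angle in degrees in `[-180, 180)`.
#' @examples
#' dihedral_angle(c(1, 0, -1), c(0, 0, 0), c(0, 0, 1), c(0, 1, 2))  # +90
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b1^2) == 0 || sum(b2^2) == 0 || sum(b3^2) == 0)
    stop_domain("consecutive points coincide: torsion undefined")
  if (sum(cross3(b1, b2)^2) < 1e-24 || sum(cross3(b2, b3)^2) < 1e-24)
    stop_domain("collinear bonded triplet: torsion undefined")
  b2h <- b2 / sqrt(sum(b2^2))
  # project the outer bonds onto the plane normal to the central bond;
  # the signed angle between the projections is the IUPAC torsion
  v <- -b1 - sum(-b1 * b2h) * b2h
  w <- b3 - sum(b3 * b2h) * b2h
  ang <- atan2(sum(cross3(b2h, v) * w), sum(v * w)) * 180 / pi
  wrap_deg(ang)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# wrap an angle in degrees onto [-180, 180)
wrap_deg <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Classify a phenyl torsion angle into cis / intermediate / trans
#'
#' Three-state classification of the phenyl-substituent torsion:
#' cis for angles in `[-60, 60)`, intermediate for `[-120, -60)` or
#' `[60, 120)`, trans for `[-180, -120)` or `[120, 180)`. The bins are
#' half-open toward increasing absolute angle so every normalized angle
#' belongs to exactly one class. Angles outside `[-180, 180)` are wrapped
#' first.
#'
#' @param angle_deg Torsion angle(s) in degrees. Vectorised.
#' @return Factor with levels `cis`, `intermediate`, `trans`.
#' @examples
#' classify_phenyl(c(18.84, -166.46, 90))
#' @export
classify_phenyl <- function(angle_deg) {
  a <- wrap_deg(angle_deg)
  cls <- ifelse(a >= -60 & a < 60, "cis",
         ifelse((a >= 60 & a < 120) | (a >= -120 & a < -60),
                "intermediate", "trans"))
  factor(cls, levels = c("cis", "intermediate", "trans"))
}

#' Geometric intramolecular hydrogen-bond detection
#'
#' A donor-H...acceptor contact counts as a hydrogen bond when the
#' H...acceptor distance is at most `d_max_A` and the donor-H...acceptor
#' angle is at least `angle_min_deg`. Defaults (2.5 angstrom, 120 degrees)
#' are the conventional moderate-strength geometric criterion; both are
#' configurable. A warning is issued if the donor-H distance exceeds 1.5
#' angstrom (not covalently plausible).
#'
#' @param donor,hydrogen,acceptor Length-3 coordinate vectors, angstrom.
#' @param d_max_A Maximum H...acceptor distance, angstrom.
#' @param angle_min_deg Minimum donor-H...acceptor angle, degrees.
#' @return Integer 0 or 1.
#' @export
detect_imhb <- function(donor, hydrogen, acceptor,
                        d_max_A = 2.5, angle_min_deg = 120) {
  if (identical(donor, acceptor) || identical(donor, hydrogen) ||
      identical(hydrogen, acceptor))
    stop_domain("donor, hydrogen and acceptor must be distinct atoms")
  dh <- sqrt(sum((hydrogen - donor)^2))
  if (dh >= 1.5)
    warning("donor-H distance ", format(dh, digits = 3),
            " A exceeds 1.5 A: check the selection", call. = FALSE)
  ha <- sqrt(sum((acceptor - hydrogen)^2))
  if (ha > d_max_A) return(0L)
  v1 <- donor - hydrogen
  v2 <- acceptor - hydrogen
  ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                             sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  as.integer(ang >= angle_min_deg)
}

#' Radius of gyration of one frame
#'
#' Mass-weighted root-mean-square distance of the atoms from their center
#' of mass; translation- and rotation-invariant, and a standard measure of
#' how folded or extended a conformation is.
#'
#' @param coords n x 3 coordinate matrix, angstrom.
#' @param masses Atomic masses, amu; unit masses by default.
#' @return Radius of gyration in angstrom.
#' @examples
#' sq <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
#' radius_of_gyration(sq)  # sqrt(2)
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop_domain("need at least one atom")
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  if (length(masses) != nrow(coords) || any(masses <= 0))
    stop_domain("masses must be positive and aligned with coordinates")
  com <- colSums(coords * masses) / sum(masses)
  d2 <- rowSums(sweep(coords, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' Minimal RMSD after optimal rigid-body superposition
#'
#' Kabsch superposition: the rotation minimizing the (optionally weighted)
#' RMSD between two conformations is obtained from the SVD of the weighted
#' covariance matrix, restricted to proper rotations (no reflections).
#'
#' @param X,Y n x 3 coordinate matrices, angstrom, with n >= 3 atoms in
#'   one-to-one correspondence.
#' @param weights Optional per-atom weights (e.g. masses); unweighted by
#'   default.
#' @return Minimal RMSD in angstrom.
#' @export
rmsd_after_superposition <- function(X, Y, weights = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y) || ncol(X) != 3 || ncol(Y) != 3)
    stop_domain("X and Y must be aligned n x 3 matrices")
  if (nrow(X) < 3) stop_domain("need at least 3 atoms")
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop_domain("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  Xc <- sweep(X, 2, colSums(X * w))
  Yc <- sweep(Y, 2, colSums(Y * w))
  if (sum(Xc^2) == 0 && sum(Yc^2) == 0)
    stop_domain("degenerate coordinates: all points coincident")
  H <- t(Xc * w) %*% Yc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  diff <- Yc - Xc %*% t(R)
  sqrt(sum(w * rowSums(diff^2)))
}

#' Per-frame conformational descriptor series for a trajectory
#'
#' Runs the full descriptor set over every frame: signed phenyl torsion,
#' three-state classification, hydrogen-bond flag, and radius of gyration.
#' Selections name the torsion quadruple and the donor / hydrogen /
#' acceptor atoms by 0-based index (see [read_selections()]).
#'
#' @param traj A `"trajectory"` object (see [read_trajectory()] or
#'   [gen_toy_conformer()]).
#' @param d_max_A,angle_min_deg Hydrogen-bond criterion, passed to
#'   [detect_imhb()].
#' @return A data.frame of class `"conformer_series"` with columns `frame`,
#'   `angle_deg`, `class`, `imhb`, `r_gyr_A`.
#' @export
conformer_state_series <- function(traj, d_max_A = 2.5, angle_min_deg = 120) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- traj$selections
  need <- c("phenyl_dihedral", "imhb_donor", "imhb_hydrogen", "imhb_acceptor")
  missing <- setdiff(need, names(sel))
  if (length(missing))
    stop_domain("selections missing: %s", paste(missing, collapse = ", "))
  quad <- sel$phenyl_dihedral + 1L # stored 0-based
  dha <- c(sel$imhb_donor, sel$imhb_hydrogen, sel$imhb_acceptor) + 1L
  n <- traj$n_frames
  angle <- numeric(n); imhb <- integer(n); rg <- numeric(n)
  for (i in seq_len(n)) {
    fr <- traj$coordinates[[i]]
    angle[i] <- dihedral_angle(fr[quad[1], ], fr[quad[2], ],
                               fr[quad[3], ], fr[quad[4], ])
    imhb[i] <- detect_imhb(fr[dha[1], ], fr[dha[2], ], fr[dha[3], ],
                           d_max_A = d_max_A, angle_min_deg = angle_min_deg)
    rg[i] <- radius_of_gyration(fr, traj$masses)
  }
  out <- data.frame(frame = seq_len(n), angle_deg = angle,
                    class = classify_phenyl(angle), imhb = imhb,
                    r_gyr_A = rg)
  class(out) <- c("conformer_series", class(out))
  out
}

#' Joint population table of phenyl class and hydrogen-bond state
#'
#' Counts and fractions over the 3 x 2 grid of phenyl class (cis /
#' intermediate / trans) by hydrogen-bond flag (0 / 1); fractions sum to 1
#' and marginals are provided for comparison with per-descriptor
#' histograms.
#'
#' @param series A data.frame with columns `class` and `imhb` (e.g. from
#'   [conformer_state_series()] or [gen_dihedral_series()]).
#' @return A list of class `"population_table"` with `counts`, `fractions`
#'   (3 x 2 matrices), `class_marginal`, `imhb_marginal`, `n_frames`.
#' @export
population_table <- function(series) {
  if (is.null(series) || nrow(series) == 0)
    stop_domain("empty descriptor series")
  cls <- factor(series$class, levels = c("cis", "intermediate", "trans"))
  hb <- factor(series$imhb, levels = c(0, 1))
  counts <- table(class = cls, imhb = hb)
  fractions <- counts / sum(counts)
  structure(list(counts = unclass(counts),
                 fractions = unclass(fractions),
                 class_marginal = rowSums(fractions),
                 imhb_marginal = colSums(fractions),
                 n_frames = nrow(series)),
            class = "population_table")
}

#' @export
print.population_table <- function(x, ...) {
  cat("Joint phenyl-class x IMHB populations over", x$n_frames, "frames\n")
  print(round(x$fractions, 4))
  invisible(x)
}
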