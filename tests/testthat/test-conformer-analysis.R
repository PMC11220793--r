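test_that("dihedral angle follows the signed torsion convention", {
  # planar syn: far atoms on the same side -> 0
  expect_equal(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1),
                              c(1, 0, 1)), 0)
  # planar anti maps to -180 in the half-open domain
  expect_equal(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1),
                              c(-1, 0, 1)), -180)
  # constructed right-handed geometry -> +90
  expect_equal(dihedral_angle(c(1, 0, -1), c(0, 0, 0), c(0, 0, 1),
                              c(0, 1, 2)), 90)
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1),
                              c(0, 1, 2)), "coincide")
  expect_error(dihedral_angle(c(0, 0, -1), c(0, 0, 0), c(0, 0, 1),
                              c(0, 1, 2)), "collinear")
})

test_that("dihedral angle agrees with bio3d on random geometries", {
  set.seed(23)
  for (i in 1:20) {
    p <- matrix(rnorm(12, sd = 2), 4, 3, byrow = TRUE)
    ref <- bio3d::torsion.xyz(as.vector(t(p)))
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("phenyl classification reproduces the worked examples", {
  expect_equal(as.character(classify_phenyl(18.84)), "cis")
  expect_equal(as.character(classify_phenyl(-166.46)), "trans")
  expect_equal(as.character(classify_phenyl(90)), "intermediate")
  # half-open boundaries toward increasing |angle|
  expect_equal(as.character(classify_phenyl(c(60, -60, 120, -120, -180))),
               c("intermediate", "cis", "trans", "intermediate", "trans"))
})

test_that("the three classes partition the angle domain", {
  grid <- seq(-180, 180 - 0.01, by = 0.01)
  cls <- classify_phenyl(grid)
  expect_false(anyNA(cls))
  # each class occupies exactly one third of the circle
  expect_equal(unname(table(cls) / length(grid)),
               rep(1 / 3, 3), tolerance = 1e-3,
               ignore_attr = TRUE)
  # wrapping: out-of-domain input classifies like its normalized image
  expect_equal(as.character(classify_phenyl(188.84)),
               as.character(classify_phenyl(188.84 - 360)))
})

test_that("hydrogen-bond detection applies both distance and angle cutoffs", {
  H <- c(0, 0, 0); D <- c(0, 0, 0.97)
  place <- function(dist, ang) {
    a <- ang * pi / 180
    H + dist * c(sin(a), 0, cos(a))
  }
  expect_equal(detect_imhb(D, H, place(1.8, 160)), 1L)
  expect_equal(detect_imhb(D, H, place(4.0, 160)), 0L)
  # inside the distance cutoff but below the angle cutoff
  expect_equal(detect_imhb(D, H, place(2.0, 90)), 0L)
  # cutoffs are configurable
  expect_equal(detect_imhb(D, H, place(2.0, 90), angle_min_deg = 80), 1L)
  expect_error(detect_imhb(D, D, place(1.8, 160)), "distinct")
  expect_warning(detect_imhb(c(0, 0, 3), H, place(1.8, 160)), "1.5 A")
})

test_that("radius of gyration matches closed-form cases", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1)
  sq <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
  expect_equal(radius_of_gyration(sq), sqrt(2))
  # mass weighting shifts the center of mass
  expect_equal(radius_of_gyration(two, masses = c(3, 1)),
               sqrt((3 * 0.5^2 + 1 * 1.5^2) / 4))
})

test_that("superposed RMSD is zero on congruent sets and matches oracles", {
  set.seed(41)
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd_after_superposition(X, X), 0)
  R <- random_rotation()
  Y <- apply_rigid(X, R, c(3, -2, 5))
  expect_lt(rmsd_after_superposition(X, Y), 1e-9)
  # agreement with bio3d's superposition on non-congruent sets
  Z <- X + 0.4 * matrix(rnorm(30), 10, 3)
  expect_equal(rmsd_after_superposition(X, Z),
               as.numeric(bio3d::rmsd(as.vector(t(X)), as.vector(t(Z)),
                                      fit = TRUE)),
               tolerance = 1e-3)
  expect_error(rmsd_after_superposition(X[1:2, ], Z[1:2, ]), "3 atoms")
})

test_that("RMSD minimum matches a brute-force rotation search", {
  # unit square vs the same square with one corner lifted 1 A out of plane
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  Y <- X; Y[3, 3] <- 1
  got <- rmsd_after_superposition(X, Y)
  # grid search over ZYZ Euler angles
  w <- rep(1 / 4, 4)
  Xc <- sweep(X, 2, colSums(X * w)); Yc <- sweep(Y, 2, colSums(Y * w))
  ang <- seq(0, 2 * pi, length.out = 73)[-73]
  half <- seq(0, pi, length.out = 37)
  rotz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                            c(0, 0, 1))
  roty <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                            c(-sin(a), 0, cos(a)))
  best <- Inf
  for (a in ang) for (b in half) for (g in ang) {
    R <- rotz(a) %*% roty(b) %*% rotz(g)
    best <- min(best, sqrt(mean(rowSums((Yc - Xc %*% t(R))^2))))
  }
  expect_equal(got, best, tolerance = 1e-3)
  expect_lte(got, best + 1e-12) # ours is the true minimum
})

test_that("descriptors are invariant under rigid motion of the trajectory", {
  set.seed(57)
  sp <- synthetic_spec()
  traj <- gen_toy_conformer(sp, torsion_deg = 37, ha_dist_A = 1.9,
                            dha_angle_deg = 150)
  base <- conformer_state_series(traj)
  for (i in 1:5) {
    R <- random_rotation(); shift <- rnorm(3, sd = 10)
    moved <- trajectory(lapply(traj$coordinates, apply_rigid, R, shift),
                        traj$atom_names, traj$masses, traj$selections)
    got <- conformer_state_series(moved)
    expect_equal(got$angle_deg, base$angle_deg, tolerance = 1e-9)
    expect_equal(got$imhb, base$imhb)
    expect_equal(got$r_gyr_A, base$r_gyr_A, tolerance = 1e-9)
    expect_lt(rmsd_after_superposition(moved$coordinates[[1]],
                                       traj$coordinates[[1]]), 1e-9)
  }
})

test_that("population tables are normalized with consistent marginals", {
  s <- data.frame(class = c("cis", "cis", "trans", "trans"),
                  imhb = c(1, 1, 0, 0))
  pt <- population_table(s)
  expect_equal(sum(pt$fractions), 1, tolerance = 1e-12)
  expect_equal(sum(pt$counts), 4)
  expect_equal(unname(pt$class_marginal["cis"]), 0.5)
  expect_equal(unname(pt$imhb_marginal["1"]), 0.5)
  all_cis <- data.frame(class = rep("cis", 10), imhb = rep(1, 10))
  expect_equal(unname(population_table(all_cis)$fractions["cis", "1"]), 1)
  expect_error(population_table(data.frame()), "empty")
  # marginalizing the joint table reproduces per-descriptor histograms
  set.seed(3)
  big <- data.frame(
    class = sample(c("cis", "intermediate", "trans"), 1000, TRUE),
    imhb = sample(0:1, 1000, TRUE))
  pt2 <- population_table(big)
  expect_equal(unname(pt2$class_marginal),
               as.numeric(table(factor(big$class,
                 c("cis", "intermediate", "trans"))) / 1000))
})
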