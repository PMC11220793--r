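# Shared fixtures and independent oracles used across test files.

# Closed-form OLS, independent of stats::lm, for cross-checking fits.
ols_oracle <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  list(slope = sl, intercept = ic)
}

# Random proper rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(coords, R, shift) {
  sweep(coords %*% t(R), 2, shift, "+")
}

# Published per-condition nucleation table, used widely as a fixture.
nuc_tbl <- ritonavir_nucleation_table()
solv_tbl <- ritonavir_solvent_properties()
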