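# Independent oracles and small utilities used across test files.
# These deliberately avoid the package's own code paths.

RT298 <- 1.987e-3 * 298.15

# naive Santoro-Bolen evaluation (independent of the fitter)
sb_oracle <- function(D, D50, m, aN, bN, aD, bD, RT = RT298) {
  e <- exp(m * (D - D50) / RT)
  ((aN + bN * D) + (aD + bD * D) * e) / (1 + e)
}

# gap-excluded pairwise identity by explicit loop (redundancy oracle)
identity_oracle <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- 0L; hit <- 0L
  for (i in seq_along(a)) {
    if (a[i] != "-" && b[i] != "-") {
      n <- n + 1L
      if (a[i] == b[i]) hit <- hit + 1L
    }
  }
  if (n == 0L) 0 else hit / n
}

# apply a rigid rotation (axis-angle about z then x) + translation
rigid_transform <- function(model, angle_z = 0.7, angle_x = 0.3,
                            shift = c(5, -3, 2)) {
  Rz <- matrix(c(cos(angle_z), -sin(angle_z), 0,
                 sin(angle_z), cos(angle_z), 0,
                 0, 0, 1), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0,
                 0, cos(angle_x), -sin(angle_x),
                 0, sin(angle_x), cos(angle_x)), 3, byrow = TRUE)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(Rx %*% Rz)
  xyz <- sweep(xyz, 2, shift, "+")
  model$atoms[, c("x", "y", "z")] <- xyz
  model
}

# minimal hand-written PDB fixture text (3 atoms)
minimal_pdb_lines <- function() c(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "ATOM      3  C   ALA A   1      10.722   6.803  -4.199  1.00  0.00           C",
  "END")
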