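# Fixtures and independent oracles shared across the suite.
# All fixtures are built in code; no binary data.

# A minimal hand-written 3-atom PDB fixture.
write_three_atom_pdb <- function(path, resname = "DA") {
  lines <- c(
    sprintf("ATOM      1  C1' %3s I   1       1.234   2.345   3.456  1.00  0.00           C", resname),
    sprintf("ATOM      2  N9  %3s I   1      -0.500   0.250  10.000  1.00  0.00           N", resname),
    sprintf("ATOM      3  P   %3s I   1       5.000  -4.321   0.001  1.00  0.00           P", resname),
    "END")
  writeLines(lines, path)
  matrix(c(1.234, 2.345, 3.456,
           -0.5, 0.25, 10,
           5, -4.321, 0.001), ncol = 3, byrow = TRUE)
}

# Multi-model PDB of the 3-atom fixture.
write_multi_model_pdb <- function(path, n_models, atoms_per_model = 3) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n_models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    for (a in seq_len(atoms_per_model)) {
      el <- c("C", "N", "P")[(a - 1) %% 3 + 1]
      writeLines(sprintf(
        "ATOM  %5d  %-3s DA  I   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        a, paste0(el, a), a + m / 10, a * 2, -a, el), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

# Bare structure from coordinate matrix (synthetic unit-test scaffold).
toy_structure <- function(xyz, element = "C", chain = "A", resno = NULL,
                          name = NULL, resname = "UNK", mass = NULL) {
  n <- nrow(xyz)
  if (is.null(resno)) resno <- rep(1L, n)
  if (is.null(name)) name <- paste0("X", seq_len(n))
  element <- rep_len(element, n)
  atoms <- data.frame(serial = seq_len(n), name = name,
                      resname = rep_len(resname, n),
                      chain = rep_len(chain, n), resno = resno,
                      element = element,
                      mass = if (is.null(mass)) element_mass(element)
                             else rep_len(mass, n),
                      occupancy = 1, bfactor = 0, stringsAsFactors = FALSE)
  ncp_structure(atoms, xyz)
}

# Trajectory from a list of coordinate matrices over a fixed topology.
toy_trajectory <- function(topology, frames) {
  co <- array(NA_real_, dim = c(nrow(topology$xyz), 3, length(frames)))
  for (t in seq_along(frames)) co[, , t] <- frames[[t]]
  ncp_trajectory(topology, co)
}

# Random proper rotation + translation (for invariance suites).
random_rigid_transform <- function() {
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 10))
}

apply_rigid <- function(xyz, rt) sweep(xyz %*% t(rt$R), 2, rt$t, "+")

# Independent quaternion-method superposition RMSD oracle (Kearsley):
# minimal RMSD is obtained from the largest eigenvalue of the 4x4
# quaternion key matrix, without constructing the rotation.
quaternion_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  M <- t(P) %*% Q
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

# Brute-force residence-frequency oracle: explicit double loop over atoms.
brute_residence <- function(traj, g_idx, s_idx, cutoff) {
  hits <- 0
  for (t in seq_len(traj$n_frames)) {
    found <- FALSE
    for (i in g_idx) for (j in s_idx) {
      d <- sqrt(sum((traj$coords[i, , t] - traj$coords[j, , t])^2))
      if (d < cutoff) found <- TRUE
    }
    hits <- hits + found
  }
  100 * hits / traj$n_frames
}

# Standard 15-bp fixture duplex; memoized per test run for speed.
.fixture_env <- new.env()
fixture_duplex <- function() {
  if (is.null(.fixture_env$st))
    .fixture_env$st <- build_bdna("GCGCATAACGCGCAT")
  .fixture_env$st
}
fixture_lesioned <- function(type = "AP") {
  key <- paste0("lesion_", type)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- apply_lesion(fixture_duplex(), 8, type)
  .fixture_env[[key]]
}
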