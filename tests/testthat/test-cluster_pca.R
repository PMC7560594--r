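test_that("Kabsch superposition is optimal, proper and oracle-consistent", {
  set.seed(21)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(P, P)$rmsd, 0, tolerance = 1e-12)
  rt <- random_rigid_transform()
  expect_lt(kabsch_superpose(apply_rigid(P, rt), P)$rmsd, 1e-8)
  # 4-atom toys against the independent quaternion-method oracle
  for (k in 1:10) {
    A <- matrix(rnorm(12), 4, 3)
    B <- matrix(rnorm(12), 4, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, quaternion_rmsd(A, B),
                 tolerance = 1e-8)
  }
  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("pairwise RMSD matches a per-pair superposition oracle", {
  st <- fixture_lesioned("AP")
  fl <- flip_spec(8, "I", mode = "exact_fraction", fraction = 0.4)
  tr <- simulate_flip_dynamics(st, list(fl), n_frames = 8, seed = 2,
                               noise_sigma = 0.2)
  sel <- select_atoms(tr$topology, heavy = TRUE)
  M <- pairwise_rmsd(tr, sel)
  expect_equal(diag(unclass(M)), rep(0, 8))
  expect_equal(unclass(M), t(unclass(M)))
  for (i in 1:7) for (j in (i + 1):8) {
    A <- matrix(tr$coords[sel, , i], ncol = 3)
    B <- matrix(tr$coords[sel, , j], ncol = 3)
    expect_equal(M[i, j], quaternion_rmsd(A, B), tolerance = 1e-8)
  }
  # identical frames -> all zeros; single frame -> 1x1 zero
  tr_id <- toy_trajectory(st, list(st$xyz, st$xyz, st$xyz))
  expect_true(all(unclass(pairwise_rmsd(tr_id, sel)) < 1e-12))
  tr_one <- toy_trajectory(st, list(st$xyz))
  expect_equal(dim(unclass(pairwise_rmsd(tr_one, sel))), c(1, 1))
})

test_that("clustering recovers designed conformer splits and occupancies", {
  st <- fixture_lesioned("AP")
  sel <- select_atoms(st, chain = "I", resno = 6:10, heavy = TRUE)
  # two well-separated conformers, 80/45 frames (64.0% / 36.0%)
  fl <- flip_spec(8, "I", mode = "exact_fraction", fraction = 45 / 125)
  tr <- simulate_flip_dynamics(st, list(fl), n_frames = 125, seed = 3,
                               noise_sigma = 0.05)
  cl <- cluster_frames(pairwise_rmsd(tr, sel), k = 2)
  expect_equal(unname(cl$occupancy), c(64, 36))
  truth <- attr(tr$states, "wide")[, 1]
  expect_equal(unname(cl$labels[truth]), rep(2, 45))
  # dominant-cluster split 249/1 (99.6% / 0.4%)
  fl2 <- flip_spec(8, "I", mode = "exact_fraction", fraction = 1 / 250)
  tr2 <- simulate_flip_dynamics(st, list(fl2), n_frames = 250, seed = 4,
                                noise_sigma = 0.05)
  cl2 <- cluster_frames(pairwise_rmsd(tr2, sel), k = 2)
  expect_equal(unname(cl2$occupancy), c(99.6, 0.4))
  # all-identical frames collapse to one full cluster
  tr_id <- toy_trajectory(st, rep(list(st$xyz), 6))
  cl_id <- cluster_frames(pairwise_rmsd(tr_id, sel), eps = 2.5)
  expect_equal(unname(cl_id$occupancy), 100)
  expect_equal(sum(cl$occupancy), 100)
  expect_error(cluster_frames(pairwise_rmsd(tr_id, sel), eps = -1),
               "positive")
  expect_error(cluster_frames(pairwise_rmsd(tr_id, sel), k = 0), "k must")
})

test_that("medoids minimize mean intra-cluster RMSD with index tie-break", {
  M <- matrix(c(0, 1, 4,
                1, 0, 2,
                4, 2, 0), 3, 3)
  # brute-force argmin of mean RMSD to other members
  means <- sapply(1:3, function(i) mean(M[i, -i]))
  expect_equal(representative_frame(1:3, M), which.min(means))
  expect_equal(representative_frame(5L, M), 5L)
  tie <- matrix(0, 2, 2)
  expect_equal(representative_frame(1:2, tie), 1L)
  expect_error(representative_frame(integer(0), M), "empty")
})

test_that("pair features are reciprocal distances in stable pair order", {
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0))
  st <- toy_structure(xyz, chain = "A", resno = c(1L, 2L))
  tr <- toy_trajectory(st, list(xyz, xyz))
  pf <- pair_features(tr)
  expect_equal(dim(pf$features), c(2, 1))
  expect_equal(as.vector(pf$features), c(0.2, 0.2))
  # 4 residues -> 6 lexicographic pairs
  xyz4 <- matrix(rnorm(12, sd = 4), 4, 3)
  st4 <- toy_structure(xyz4, resno = 1:4)
  pf4 <- pair_features(toy_trajectory(st4, list(xyz4)))
  expect_equal(pf4$pairs,
               rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4)))
  # internal coordinates are rigid-body invariant
  set.seed(5)
  rt <- random_rigid_transform()
  pf_mv <- pair_features(toy_trajectory(st4, list(apply_rigid(xyz4, rt))))
  expect_equal(pf_mv$features, pf4$features, tolerance = 1e-9)
  # coincident centers are rejected with frame and pair context
  xyz_bad <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))
  st_bad <- toy_structure(xyz_bad, resno = 1:3)
  expect_error(pair_features(toy_trajectory(st_bad, list(xyz_bad))),
               "frame 1")
})

test_that("PCA reproduces closed-form and brute-force covariance results", {
  # one oscillating feature among constants -> rank-1 model
  X <- cbind(a = rep(1, 40), b = sin(1:40), c = rep(2, 40))
  m <- pca_fit(X)
  expect_equal(abs(m$eigenvectors[2, 1]), 1, tolerance = 1e-8)
  expect_lt(sum(m$eigenvalues[-1]), 1e-12)
  # trace conservation: eigenvalue sum equals total variance
  set.seed(6)
  Y <- matrix(rnorm(200), 20, 10)
  mf <- pca_fit(Y)
  expect_equal(sum(mf$eigenvalues), sum(apply(Y, 2, var)), tolerance = 1e-8)
  expect_true(all(diff(mf$eigenvalues) <= 1e-12))
  # orthonormal eigenvectors
  expect_equal(crossprod(mf$eigenvectors), diag(10), tolerance = 1e-8)
  # 2x2 toy against the analytic eigenvalues
  Z <- cbind(c(1, 2, 3, 4), c(1.5, 1, 2.5, 2))
  mz <- pca_fit(Z)
  C <- stats::cov(Z)
  tr_ <- C[1, 1] + C[2, 2]; det_ <- C[1, 1] * C[2, 2] - C[1, 2]^2
  lam <- c((tr_ + sqrt(tr_^2 - 4 * det_)) / 2,
           (tr_ - sqrt(tr_^2 - 4 * det_)) / 2)
  expect_equal(mz$eigenvalues, lam, tolerance = 1e-10)
  # brute-force covariance + dense eigensolver oracle, feature-by-feature
  n <- nrow(Y)
  Cb <- matrix(0, 10, 10)
  mu <- colMeans(Y)
  for (i in 1:10) for (j in 1:10)
    Cb[i, j] <- sum((Y[, i] - mu[i]) * (Y[, j] - mu[j])) / (n - 1)
  eb <- eigen(Cb, symmetric = TRUE)
  expect_equal(mf$eigenvalues, eb$values, tolerance = 1e-8)
  # constant features -> flagged degenerate
  expect_true(pca_fit(matrix(1, 5, 3))$degenerate)
})

test_that("residue importance concentrates on the moving pair and sums to 100", {
  # 4 single-atom residues; only residue B oscillates, so only pair
  # features containing A..D vary through B's motion
  set.seed(9)
  base <- rbind(c(0, 0, 0), c(6, 0, 0), c(40, 0, 0), c(40, 6, 0))
  st <- toy_structure(base, resno = 1:4)
  frames <- lapply(1:30, function(t) {
    x <- base; x[2, 1] <- 6 + 2 * sin(t); x
  })
  tr <- toy_trajectory(st, frames)
  m <- pca_fit(pair_features(tr))
  imp <- residue_importance(m, n_components = 3)
  expect_equal(sum(imp$per_residue$percent), 100, tolerance = 1e-6)
  # the A-B pair dominates: A and B split the importance nearly evenly
  p <- imp$per_residue$percent
  expect_gt(p[1] + p[2], 85)
  expect_equal(p[1] / p[2], 1, tolerance = 0.35)
  # adding a far-away immobile residue does not disturb the A/B split
  base5 <- rbind(base, c(0, 40, 0))
  st5 <- toy_structure(base5, resno = 1:5)
  frames5 <- lapply(1:30, function(t) {
    x <- base5; x[2, 1] <- 6 + 2 * sin(t); x
  })
  imp5 <- residue_importance(pca_fit(pair_features(
    toy_trajectory(st5, frames5))), n_components = 3)
  r51 <- imp5$per_residue$percent[1] / imp5$per_residue$percent[2]
  expect_equal(r51, p[1] / p[2], tolerance = 0.1)
  expect_error(residue_importance(pca_fit(matrix(rnorm(20), 10, 2))),
               "bookkeeping")
})

test_that("the PCA pipeline is rigid-body invariant end to end", {
  st <- fixture_lesioned("AP")
  fl <- flip_spec(8, "I", mode = "exact_fraction", fraction = 0.3)
  tr <- simulate_flip_dynamics(st, list(fl), n_frames = 40, seed = 8,
                               noise_sigma = 0.1)
  sec <- extract_section(tr, duplex_site_spec(st, 8), trim = 1)
  # random rotation+translation applied per frame
  set.seed(10)
  co2 <- sec$coords
  for (t in seq_len(sec$n_frames)) {
    rt <- random_rigid_transform()
    co2[, , t] <- apply_rigid(sec$coords[, , t], rt)
  }
  sec2 <- ncp_trajectory(sec$topology, co2)
  pf1 <- pair_features(sec); pf2 <- pair_features(sec2)
  expect_equal(pf2$features, pf1$features, tolerance = 1e-8)
  m1 <- pca_fit(pf1); m2 <- pca_fit(pf2)
  expect_equal(m2$eigenvalues, m1$eigenvalues, tolerance = 1e-8)
  i1 <- residue_importance(m1); i2 <- residue_importance(m2)
  expect_equal(i2$per_residue$percent, i1$per_residue$percent,
               tolerance = 1e-6)
})
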