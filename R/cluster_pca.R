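# Ensemble analysis: Kabsch superposition, pairwise RMSD, hierarchical
# clustering with occupancies and medoid representatives, and PCA of
# internal coordinates (inverse distances between residue geometric
# centers) with per-residue importance.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation of `mobile` onto `reference`,
#' restricted to proper rotations (no reflection).
#'
#' @param mobile,reference coordinate matrices (atoms x 3), equal sizes.
#' @param atom_sel optional integer indices of the atoms used for the fit;
#'   the transform is applied to all atoms of `mobile`.
#' @return list with `coords` (transformed mobile) and `rmsd` (Angstrom,
#'   over the fit atoms).
#' @export
kabsch_superpose <- function(mobile, reference, atom_sel = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            all(dim(mobile) == dim(reference)))
  sel <- if (is.null(atom_sel)) seq_len(nrow(mobile)) else atom_sel
  if (length(sel) < 3) .stopf("superposition needs at least 3 atoms")
  P <- mobile[sel, , drop = FALSE]
  Q <- reference[sel, , drop = FALSE]
  sv <- svd(sweep(P, 2, colMeans(P)))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    .stopf("superposition atoms are (nearly) collinear")
  rt <- .kabsch_rt(P, Q)
  out <- .apply_rt(mobile, rt)
  list(coords = out,
       rmsd = sqrt(mean(rowSums((out[sel, , drop = FALSE] - Q)^2))))
}

#' Pairwise RMSD matrix of a trajectory
#'
#' RMSD after per-pair optimal superposition, by default over all heavy
#' atoms of the (already extracted) section. Note that RMSD after
#' independent pairwise superposition need not satisfy the triangle
#' inequality.
#'
#' @param traj an `ncp_trajectory`.
#' @param atom_sel atom indices used for superposition and RMSD; default
#'   all heavy atoms.
#' @return an `rmsd_matrix`: symmetric `n_frames x n_frames` matrix with
#'   zero diagonal, with the selection description as an attribute.
#' @export
pairwise_rmsd <- function(traj, atom_sel = NULL) {
  stopifnot(inherits(traj, "ncp_trajectory"))
  if (is.null(atom_sel))
    atom_sel <- select_atoms(traj$topology, heavy = TRUE)
  .require_atoms(atom_sel, "pairwise RMSD atom selection")
  n <- traj$n_frames
  frames <- lapply(seq_len(n), function(t)
    matrix(traj$coords[atom_sel, , t], ncol = 3))
  M <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        M[i, j] <- M[j, i] <-
          kabsch_superpose(frames[[i]], frames[[j]])$rmsd
      }
    }
  }
  structure(M, class = c("rmsd_matrix", "matrix"),
            atom_selection = sprintf("%d atoms", length(atom_sel)))
}

#' Cluster trajectory frames on an RMSD matrix
#'
#' Average-linkage hierarchical clustering cut either at RMSD height
#' `eps` or into exactly `k` clusters. Clusters are relabelled by
#' decreasing size (ties by lowest member frame index), so cluster 1 is
#' always the dominant conformation. Occupancies are percentages of all
#' frames; medoids minimize the mean RMSD to the other cluster members.
#'
#' @param rmsd an `rmsd_matrix` (or plain symmetric matrix).
#' @param eps RMSD cut height in Angstrom (used if `k` is `NULL`).
#' @param k fixed number of clusters.
#' @return a `cluster_result`: `labels` (per frame), `occupancy` (named
#'   percent vector), `medoid` (named frame-index vector).
#' @export
cluster_frames <- function(rmsd, eps = 2.5, k = NULL) {
  M <- unclass(rmsd)
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  n <- nrow(M)
  if (is.null(k)) {
    if (eps <= 0) .stopf("cluster cut height eps must be positive")
  } else if (k < 1 || k > n) .stopf("k must lie in 1..%d", n)
  if (n == 1) {
    labels <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(M), method = "average")
    labels <- if (is.null(k)) stats::cutree(hc, h = eps)
              else stats::cutree(hc, k = k)
  }
  # relabel by decreasing size, ties by lowest member index
  sizes <- table(labels)
  first <- vapply(names(sizes), function(l) min(which(labels == l)), 0)
  ord <- order(-as.vector(sizes), first)
  relab <- stats::setNames(seq_along(ord), names(sizes)[ord])
  labels <- unname(relab[as.character(labels)])
  occ <- 100 * as.vector(table(labels)) / n
  names(occ) <- seq_along(occ)
  med <- vapply(seq_along(occ), function(cl)
    representative_frame(which(labels == cl), M), 0L)
  names(med) <- names(occ)
  structure(list(labels = labels, occupancy = occ, medoid = med),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters: %s\n", length(x$occupancy),
              paste(sprintf("#%s %.1f%% (medoid %d)", names(x$occupancy),
                            x$occupancy, x$medoid), collapse = ", ")))
  invisible(x)
}

#' Medoid (representative) frame of a cluster
#'
#' @param members frame indices of the cluster.
#' @param rmsd the RMSD matrix.
#' @return the member minimizing mean RMSD to the other members (lowest
#'   index on ties).
#' @export
representative_frame <- function(members, rmsd) {
  M <- unclass(rmsd)
  if (length(members) == 0) .stopf("empty cluster")
  if (length(members) == 1) return(as.integer(members))
  sub <- M[members, members, drop = FALSE]
  mean_r <- rowSums(sub) / (length(members) - 1)
  as.integer(members[which.min(mean_r)])  # which.min takes the first tie
}

# ---------------------------------------------------------------------------
# Internal-coordinate PCA

#' Inverse-distance pair features of a trajectory
#'
#' For every unordered pair of selected residues, the per-frame inverse
#' distance between their geometric centers (unweighted mean of heavy-atom
#' coordinates). Internal coordinates are rigid-body invariant, which
#' avoids the superposition dependence of Cartesian-coordinate PCA.
#'
#' @param traj an `ncp_trajectory`.
#' @param residues data.frame with columns `chain`, `resno` (rows in the
#'   desired residue order), e.g. from [residue_table()]; default: all
#'   residues of the topology.
#' @return a `pair_features` object: `features` (frames x pairs matrix,
#'   Angstrom^-1), `pairs` (2-column index matrix into `residues`),
#'   `residues`.
#' @export
pair_features <- function(traj, residues = NULL) {
  stopifnot(inherits(traj, "ncp_trajectory"))
  top <- traj$topology
  if (is.null(residues)) residues <- residue_table(top)
  nr <- nrow(residues)
  if (nr < 2) .stopf("pair features need at least 2 residues")
  idx <- lapply(seq_len(nr), function(r)
    .require_atoms(select_atoms(top, chain = residues$chain[r],
                                resno = residues$resno[r], heavy = TRUE),
                   sprintf("heavy atoms of residue %s:%d",
                           residues$chain[r], residues$resno[r])))
  pairs <- t(utils::combn(nr, 2))   # lexicographic order
  nf <- traj$n_frames
  centers <- array(NA_real_, dim = c(nr, 3, nf))
  for (r in seq_len(nr))
    centers[r, , ] <- apply(traj$coords[idx[[r]], , , drop = FALSE], c(2, 3),
                            mean)
  feats <- matrix(NA_real_, nf, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    A <- matrix(centers[pairs[p, 1], , ], nrow = 3)
    B <- matrix(centers[pairs[p, 2], , ], nrow = 3)
    d <- sqrt(colSums((A - B)^2))
    if (any(d < 1e-9)) {
      t_bad <- which(d < 1e-9)[1]
      .stopf("coincident residue centers in frame %d (pair %d-%d)",
             t_bad, pairs[p, 1], pairs[p, 2])
    }
    feats[, p] <- 1 / d
  }
  colnames(feats) <- apply(pairs, 1, function(pr)
    sprintf("%s:%d|%s:%d", residues$chain[pr[1]], residues$resno[pr[1]],
            residues$chain[pr[2]], residues$resno[pr[2]]))
  structure(list(features = feats, pairs = pairs, residues = residues),
            class = "pair_features")
}

#' Principal component analysis of pair features
#'
#' Mean-centers the features over frames, forms the covariance matrix and
#' diagonalizes it. Components are sorted by decreasing eigenvalue;
#' eigenvalues are clamped at zero within numerical tolerance. A model
#' whose total variance is (numerically) zero is flagged `degenerate`.
#'
#' @param features a `pair_features` object or a plain frames x features
#'   matrix.
#' @return a `pca_model`: `eigenvalues`, `eigenvectors` (columns are
#'   components over features), `feature_mean`, `pairs`, `residues`,
#'   `degenerate`.
#' @export
pca_fit <- function(features) {
  pf <- NULL
  if (inherits(features, "pair_features")) {
    pf <- features; X <- features$features
  } else X <- as.matrix(features)
  if (nrow(X) < 2) .stopf("PCA needs at least 2 frames")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(X) - 1)
  eg <- eigen(C, symmetric = TRUE)
  ev <- eg$values
  ev[ev < 0 & ev > -1e-10 * max(abs(ev), 1)] <- 0
  structure(list(eigenvalues = ev, eigenvectors = eg$vectors,
                 feature_mean = mu,
                 pairs = if (!is.null(pf)) pf$pairs,
                 residues = if (!is.null(pf)) pf$residues,
                 degenerate = sum(ev) < 1e-12),
            class = "pca_model")
}

#' Per-residue importance from the leading principal components
#'
#' For each residue, the eigenvalue-weighted sum of squared component
#' loadings of every pair feature containing that residue, over the first
#' `n_components` components, normalized to percentages summing to 100.
#' Each pair feature contributes to both of its residues. The default
#' absolute-value loadings aggregate a residue's coordinated feature
#' changes; `loading = "squared"` (variance-contribution reading)
#' concentrates the map on the single largest-variance feature, which
#' pushes the stacking neighbours of a flipped base above a base-less
#' abasic residue (see the methods vignette). With
#' `weighting = "uniform"` the eigenvalue weights are replaced by equal
#' weights.
#'
#' @param model a `pca_model` fitted on `pair_features` (residue/pair
#'   bookkeeping required).
#' @param n_components number of leading components (default 10, capped at
#'   the number of available components).
#' @param weighting `"eigenvalue"` or `"uniform"`.
#' @param loading `"squared"` or `"absolute"`.
#' @return a `residue_importance`: data.frame `per_residue` (`chain`,
#'   `resno`, `percent`) plus `n_components_used`.
#' @export
residue_importance <- function(model, n_components = 10L,
                               weighting = c("eigenvalue", "uniform"),
                               loading = c("absolute", "squared")) {
  weighting <- match.arg(weighting)
  loading <- match.arg(loading)
  stopifnot(inherits(model, "pca_model"))
  if (is.null(model$pairs))
    .stopf("model lacks residue bookkeeping; fit it on pair_features()")
  ncomp <- min(n_components, length(model$eigenvalues))
  if (ncomp < 1) .stopf("no components available")
  ev <- model$eigenvalues[seq_len(ncomp)]
  w <- if (weighting == "eigenvalue") {
    if (sum(ev) <= 0) .stopf("degenerate model: zero total variance")
    ev / sum(ev)
  } else rep(1 / ncomp, ncomp)
  L <- model$eigenvectors[, seq_len(ncomp), drop = FALSE]
  Lw <- if (loading == "squared") L^2 else abs(L)
  feat_score <- as.vector(Lw %*% w)
  nr <- nrow(model$residues)
  raw <- numeric(nr)
  for (p in seq_len(nrow(model$pairs))) {
    raw[model$pairs[p, 1]] <- raw[model$pairs[p, 1]] + feat_score[p]
    raw[model$pairs[p, 2]] <- raw[model$pairs[p, 2]] + feat_score[p]
  }
  if (sum(raw) <= 0) .stopf("degenerate model: all-zero importance")
  structure(list(per_residue = data.frame(chain = model$residues$chain,
                                          resno = model$residues$resno,
                                          percent = 100 * raw / sum(raw),
                                          stringsAsFactors = FALSE),
                 n_components_used = ncomp),
            class = "residue_importance")
}

#' @export
print.residue_importance <- function(x, ...) {
  top <- x$per_residue[order(-x$per_residue$percent), ][1:min(5,
    nrow(x$per_residue)), ]
  cat(sprintf("<residue_importance> %d residues, %d components; top: %s\n",
              nrow(x$per_residue), x$n_components_used,
              paste(sprintf("%s:%d %.1f%%", top$chain, top$resno,
                            top$percent), collapse = ", ")))
  invisible(x)
}

#' Export a residue-importance map
#'
#' Writes a CSV (`chain`, `resno`, `percent`) and, optionally, a PDB copy
#' of a structure with the per-residue percentage painted into the
#' B-factor column for molecular viewers (color scale annotated in the
#' header metadata of the CSV).
#'
#' @param importance a `residue_importance`.
#' @param csv_path CSV output path.
#' @param structure optional `ncp_structure` to paint.
#' @param pdb_path PDB output path (required with `structure`).
#' @export
write_importance <- function(importance, csv_path, structure = NULL,
                             pdb_path = NULL) {
  stopifnot(inherits(importance, "residue_importance"))
  utils::write.csv(importance$per_residue, csv_path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(structure)) {
    if (is.null(pdb_path)) .stopf("pdb_path required to paint a structure")
    b <- structure$atoms$bfactor
    for (r in seq_len(nrow(importance$per_residue))) {
      sel <- structure$atoms$chain == importance$per_residue$chain[r] &
        structure$atoms$resno == importance$per_residue$resno[r]
      b[sel] <- importance$per_residue$percent[r]
    }
    st <- structure; st$atoms$bfactor <- b
    write_structure(st, pdb_path)
  }
  invisible(csv_path)
}
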