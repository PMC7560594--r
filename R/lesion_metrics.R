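# Per-site geometric descriptors: extrahelicity (C1'-C1' distance),
# orphan-base ejection (nucleobase COM distance), section bend angle,
# indicator correlation and replicate aggregation.

#' Threshold configuration for the lesion descriptors
#'
#' @param extrahelical_c1p_threshold C1'-C1' distance (Angstrom) above
#'   which the lesion is classified extrahelical.
#' @param ejection_com_threshold COM distance above which the orphan base
#'   is classified ejected.
#' @param canonical_com_reference COM distance of a canonical
#'   Watson-Crick pair under the package's default ejection-descriptor
#'   atom subset (reporting metadata).
#' @param contact_cutoff distance below which a charged group is in
#'   contact with the damaged site.
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(extrahelical_c1p_threshold = 14.0,
                             ejection_com_threshold = 10.0,
                             canonical_com_reference = 6.8,
                             contact_cutoff = 6.0) {
  v <- c(extrahelical_c1p_threshold, ejection_com_threshold,
         canonical_com_reference, contact_cutoff)
  if (any(v <= 0)) .stopf("all thresholds must be positive")
  if (ejection_com_threshold <= canonical_com_reference)
    .stopf("ejection threshold must exceed the canonical COM reference")
  structure(list(extrahelical_c1p_threshold = extrahelical_c1p_threshold,
                 ejection_com_threshold = ejection_com_threshold,
                 canonical_com_reference = canonical_com_reference,
                 contact_cutoff = contact_cutoff),
            class = "threshold_config")
}

#' @noRd
.distance_series <- function(values, descriptor_name, atoms_used) {
  if (any(!is.finite(values)) || any(values <= 0))
    .stopf("%s: distances must be positive and finite", descriptor_name)
  structure(list(values = values, descriptor_name = descriptor_name,
                 atoms_used = atoms_used, n_frames = length(values)),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %s: %d frames, mean %.2f A (%s)\n",
              x$descriptor_name, x$n_frames, mean(x$values), x$atoms_used))
  invisible(x)
}

#' Per-frame C1'-C1' distance between a lesion and its facing nucleotide
#'
#' The extrahelicity criterion of abasic sites is defined on the distance
#' between the lesion's C1' atom and the facing nucleotide's C1' atom;
#' abasic residues retain C1' even though the base is absent.
#'
#' @param traj an `ncp_trajectory`.
#' @param spec a [site_spec()] (uses `$lesion` and `$facing`).
#' @return a `distance_series`.
#' @export
c1p_distance_series <- function(traj, spec) {
  stopifnot(inherits(traj, "ncp_trajectory"), inherits(spec, "site_spec"))
  top <- traj$topology
  ia <- select_atoms(top, chain = spec$lesion$chain,
                     resno = spec$lesion$resno, name = "C1'")
  ib <- select_atoms(top, chain = spec$facing$chain,
                     resno = spec$facing$resno, name = "C1'")
  if (length(ia) != 1)
    .stopf("residue %s:%d has no (unique) C1' atom",
           spec$lesion$chain, spec$lesion$resno)
  if (length(ib) != 1)
    .stopf("residue %s:%d has no (unique) C1' atom",
           spec$facing$chain, spec$facing$resno)
  dd <- traj$coords[ia, , , drop = FALSE] - traj$coords[ib, , , drop = FALSE]
  d <- sqrt(apply(dd^2, 3, sum))
  .distance_series(d, sprintf("C1'-C1' %s", spec$label),
                   sprintf("C1'(%s:%d)-C1'(%s:%d)",
                           spec$lesion$chain, spec$lesion$resno,
                           spec$facing$chain, spec$facing$resno))
}

#' @noRd
.com_subset_idx <- function(top, chain, resno, subset) {
  heavy <- select_atoms(top, chain = chain, resno = resno, heavy = TRUE)
  a <- top$atoms
  switch(subset,
    base = select_atoms(top, chain = chain, resno = resno, base_only = TRUE),
    base_ext = heavy[!(a$name[heavy] %in%
                         setdiff(.BACKBONE_ATOMS, .BASE_EXT_KEEP))],
    heavy = heavy,
    all = select_atoms(top, chain = chain, resno = resno),
    .stopf("unknown COM subset '%s'", subset))
}

#' Per-frame center-of-mass distance between two residues
#'
#' Mass-weighted centers over a configurable atom subset. The default
#' subset `"base_ext"` -- nucleobase heavy atoms plus the sugar C1' and
#' C2' at the base attachment -- is the package's orphan-base ejection
#' descriptor, calibrated so that a canonical Watson-Crick dA:dT pair of
#' the builder sits at the 6.8 Angstrom canonical B-DNA reference (see the
#' methods vignette). `"base"` restricts to nucleobase heavy atoms only
#' and errors on abasic residues, which have no base.
#'
#' @param traj an `ncp_trajectory`.
#' @param res_a,res_b lists `list(chain=, resno=)`.
#' @param subset `"base_ext"`, `"base"`, `"heavy"` or `"all"`.
#' @return a `distance_series`.
#' @export
com_distance_series <- function(traj, res_a, res_b, subset = "base_ext") {
  stopifnot(inherits(traj, "ncp_trajectory"))
  top <- traj$topology
  ia <- .require_atoms(
    .com_subset_idx(top, res_a$chain, res_a$resno, subset),
    sprintf("%s subset of residue %s:%d", subset, res_a$chain, res_a$resno))
  ib <- .require_atoms(
    .com_subset_idx(top, res_b$chain, res_b$resno, subset),
    sprintf("%s subset of residue %s:%d", subset, res_b$chain, res_b$resno))
  ma <- top$atoms$mass[ia]; mb <- top$atoms$mass[ib]
  d <- vapply(seq_len(traj$n_frames), function(t) {
    A <- matrix(traj$coords[ia, , t], ncol = 3)
    B <- matrix(traj$coords[ib, , t], ncol = 3)
    ca <- colSums(A * ma) / sum(ma)
    cb <- colSums(B * mb) / sum(mb)
    .vnorm(ca - cb)
  }, 0)
  .distance_series(d, "COM distance",
                   sprintf("%s(%s:%d)-%s(%s:%d)", subset, res_a$chain,
                           res_a$resno, subset, res_b$chain, res_b$resno))
}

#' @noRd
.percent_above <- function(series, threshold) {
  stopifnot(inherits(series, "distance_series"))
  if (series$n_frames < 1) .stopf("empty distance series")
  100 * sum(series$values > threshold) / series$n_frames
}

#' Extrahelicity: percentage of frames beyond the C1'-C1' threshold
#'
#' Frames strictly above the threshold count as extrahelical; the
#' percentage is over all frames, which need not be consecutive. Frames
#' exactly at the threshold count as intrahelical.
#'
#' @param series a `distance_series` from [c1p_distance_series()].
#' @param cfg a [threshold_config()].
#' @return percentage in `[0, 100]` (unrounded).
#' @export
extrahelicity_percent <- function(series, cfg = threshold_config()) {
  .percent_above(series, cfg$extrahelical_c1p_threshold)
}

#' Orphan-base ejection: percentage of frames beyond the COM threshold
#'
#' @param series a `distance_series` from [com_distance_series()].
#' @param cfg a [threshold_config()].
#' @return percentage in `[0, 100]` (unrounded).
#' @export
ejection_fraction <- function(series, cfg = threshold_config()) {
  .percent_above(series, cfg$ejection_com_threshold)
}

# ---------------------------------------------------------------------------
# Bend angle

# Base-pair plane normal from the base heavy atoms of both pair residues
# (either residue suffices if the other is abasic).
#' @noRd
.pair_normal <- function(xyz) {
  X <- sweep(xyz, 2, colMeans(xyz))
  svd(X)$v[, 3]
}

#' Per-frame bend angle of a duplex section
#'
#' A simplified curvature measure: the angle between the best-fit
#' nucleobase-plane normals of the first and the last base pair of the
#' section, both oriented along the 5'-to-3' progression of strand I. For
#' an ideal straight duplex every base-pair normal is the helix-axis
#' direction, so the metric reads (near) zero regardless of helical twist
#' phase; on an arc-bent duplex it recovers the designed end-tangent
#' angle. Optionally the first/last `end_pairs > 1` normals are averaged
#' and the angle is rescaled by `(n-1)/(n-end_pairs)` (exact for uniform
#' curvature), which damps per-frame noise.
#'
#' @param traj an `ncp_trajectory` of a duplex section.
#' @param spec a [site_spec()] giving the section bounds (pairing is k-th
#'   residue of strand I with k-th-from-the-end residue of strand J).
#' @param end_pairs number of terminal base pairs averaged per end.
#' @return an object of class `angle_series` with `values` (degrees),
#'   `mean` and `std`.
#' @export
bend_angle_series <- function(traj, spec, end_pairs = 1L) {
  stopifnot(inherits(traj, "ncp_trajectory"), inherits(spec, "site_spec"))
  top <- traj$topology
  res_i <- seq(spec$section_i$from, spec$section_i$to)
  res_j <- seq(spec$section_j$from, spec$section_j$to)
  n <- length(res_i)
  if (length(res_j) != n)
    .stopf("section strands have different lengths (%d vs %d)",
           n, length(res_j))
  if (n < 10) .stopf("bend angle needs a section of >= 10 base pairs")
  if (end_pairs < 1 || 2 * end_pairs > n - 2)
    .stopf("end_pairs out of range")
  pair_base_idx <- function(k) {
    bi <- select_atoms(top, chain = spec$section_i$chain, resno = res_i[k],
                       base_only = TRUE)
    bj <- select_atoms(top, chain = spec$section_j$chain,
                       resno = rev(res_j)[k], base_only = TRUE)
    idx <- c(bi, bj)
    if (length(idx) < 3)
      .stopf("base pair %d of section '%s' has too few base atoms for a plane",
             k, spec$label)
    idx
  }
  pair_c1_idx <- function(k) {
    c(select_atoms(top, chain = spec$section_i$chain, resno = res_i[k],
                   name = "C1'"),
      select_atoms(top, chain = spec$section_j$chain, resno = rev(res_j)[k],
                   name = "C1'"))
  }
  head_idx <- lapply(seq_len(end_pairs), pair_base_idx)
  tail_idx <- lapply(n - end_pairs + seq_len(end_pairs), pair_base_idx)
  c1_first <- pair_c1_idx(1)
  c1_last <- pair_c1_idx(n)
  scale <- (n - 1) / (n - end_pairs)
  vals <- vapply(seq_len(traj$n_frames), function(t) {
    fr <- traj$coords[, , t]
    prog <- colMeans(fr[c1_last, , drop = FALSE]) -
      colMeans(fr[c1_first, , drop = FALSE])
    orient <- function(nv) if (sum(nv * prog) < 0) -nv else nv
    mean_normal <- function(idx_list) {
      nv <- rowMeans(vapply(idx_list, function(ii)
        orient(.pair_normal(fr[ii, , drop = FALSE])), numeric(3)))
      nv / .vnorm(nv)
    }
    ang <- .angle_deg(mean_normal(head_idx), mean_normal(tail_idx)) * scale
    min(ang, 180 - 1e-9)
  }, 0)
  structure(list(values = vals, mean = mean(vals), std = stats::sd(vals)),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %d frames: %.1f +/- %.1f degrees\n",
              length(x$values), x$mean,
              ifelse(is.na(x$std), 0, x$std)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Indicator correlation and replicate aggregation

#' Phi coefficient of two thresholded indicator series
#'
#' Classifies each series by its strict threshold and returns the Pearson
#' correlation of the two boolean indicators (the phi coefficient), used
#' to quantify the coupling between lesion extrahelicity and orphan-base
#' ejection. Returns `NA` (with a warning) when either indicator is
#' constant, for which phi is undefined.
#'
#' @param series_a,series_b `distance_series` objects of equal length.
#' @param threshold_a,threshold_b strict classification thresholds.
#' @return phi in `[-1, 1]`, or `NA_real_`.
#' @export
correlate_indicators <- function(series_a, series_b, threshold_a,
                                 threshold_b) {
  stopifnot(inherits(series_a, "distance_series"),
            inherits(series_b, "distance_series"))
  if (series_a$n_frames != series_b$n_frames)
    .stopf("indicator series have different lengths (%d vs %d)",
           series_a$n_frames, series_b$n_frames)
  a <- series_a$values > threshold_a
  b <- series_b$values > threshold_b
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    warning("phi coefficient undefined: constant indicator", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(as.numeric(a), as.numeric(b))
}

#' Aggregate per-replicate percentages into a summary row
#'
#' The "All" value is the equal-weight arithmetic mean over replicates
#' (replicates have equal simulated length), rounded half-away-from-zero
#' to `decimals` as in printed tables; rounding is applied last.
#'
#' @param per_replicate named numeric vector (or list) of percentages.
#' @param decimals decimals of the rounded summary.
#' @return an object of class `percent_summary` with `per_replicate`,
#'   `all_mean`, `all_std` and `rounding`.
#' @export
aggregate_replicates <- function(per_replicate, decimals = 1L) {
  x <- unlist(per_replicate)
  if (length(x) == 0) .stopf("no replicates to aggregate")
  if (any(x < -1e-9 | x > 100 + 1e-9))
    .stopf("percentages must lie in [0, 100]")
  structure(list(per_replicate = x,
                 all_mean = round_half_up(mean(x), decimals),
                 all_std = if (length(x) > 1) stats::sd(x) else 0,
                 rounding = as.integer(decimals)),
            class = "percent_summary")
}

#' @export
print.percent_summary <- function(x, ...) {
  cat(sprintf("All: %.1f%%  (%s)\n", x$all_mean,
              paste(sprintf("%s: %.1f", names(x$per_replicate),
                            x$per_replicate), collapse = ", ")))
  invisible(x)
}

#' Occupancy-table report (one row per site and replicate, plus "All")
#'
#' @param rows named list: each element a [aggregate_replicates()] result;
#'   names are row labels (e.g. `"AP (site2)"`).
#' @param path optional CSV output path.
#' @return data.frame in wide table layout (`All`, one column per
#'   replicate), invisibly written to `path` if given.
#' @export
occupancy_table <- function(rows, path = NULL) {
  stopifnot(length(rows) > 0)
  reps <- names(rows[[1]]$per_replicate)
  tab <- do.call(rbind, lapply(names(rows), function(nm) {
    s <- rows[[nm]]
    dec <- s$rounding
    vals <- round_half_up(s$per_replicate[reps], dec)
    data.frame(system = nm, all = s$all_mean,
               as.list(stats::setNames(vals, reps)),
               stringsAsFactors = FALSE, check.names = FALSE)
  }))
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE,
                                       quote = FALSE)
  tab
}
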