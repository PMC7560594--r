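# Residence frequencies of positively charged histone-tail groups near the
# damaged site -- the geometric precursors of DNA-protein cross-links.

#' Find charged amino groups in protein chains
#'
#' Detects, per selected chain: lysine side-chain amines (`LYS_NZ`, the NZ
#' atom), arginine guanidinium groups (`ARG_GUANIDINIUM`, atoms NE, NH1,
#' NH2) and the N-terminal backbone amine of the chain (`NTERM_N`, the
#' first residue's N). Groups are returned in deterministic
#' (chain, residue number) order.
#'
#' @param structure an `ncp_structure`.
#' @param chains chains to scan.
#' @return list of `charged_group` objects (fields `chain`, `resno`,
#'   `resname`, `kind`, `atom_idx`); empty list if the chains contain no
#'   protein residues.
#' @export
find_charged_groups <- function(structure, chains) {
  stopifnot(inherits(structure, "ncp_structure"))
  a <- structure$atoms
  groups <- list()
  for (ch in sort(chains)) {
    rows <- which(a$chain == ch)
    if (length(rows) == 0) .stopf("chain '%s' not present", ch)
    res <- unique(a[rows, c("resno", "resname")])
    res <- res[order(res$resno), ]
    is_protein <- a$name[rows] %in% c("CA", "N", "C", "O")
    if (!any(is_protein)) next
    # N-terminal amine of the chain
    first <- res$resno[1]
    n_idx <- which(a$chain == ch & a$resno == first & a$name == "N")
    if (length(n_idx) == 1)
      groups[[length(groups) + 1]] <- structure(
        list(chain = ch, resno = first,
             resname = res$resname[1], kind = "NTERM_N",
             atom_idx = n_idx), class = "charged_group")
    for (r in seq_len(nrow(res))) {
      rn <- res$resname[r]; ri <- res$resno[r]
      if (rn == "LYS") {
        nz <- which(a$chain == ch & a$resno == ri & a$name == "NZ")
        if (length(nz) != 1)
          .stopf("lysine %s:%d lacks its NZ atom", ch, ri)
        groups[[length(groups) + 1]] <- structure(
          list(chain = ch, resno = ri, resname = rn, kind = "LYS_NZ",
               atom_idx = nz), class = "charged_group")
      } else if (rn == "ARG") {
        gu <- which(a$chain == ch & a$resno == ri &
                      a$name %in% c("NE", "NH1", "NH2"))
        if (length(gu) != 3)
          .stopf("arginine %s:%d lacks guanidinium atoms (found %d of 3)",
                 ch, ri, length(gu))
        groups[[length(groups) + 1]] <- structure(
          list(chain = ch, resno = ri, resname = rn,
               kind = "ARG_GUANIDINIUM", atom_idx = gu),
          class = "charged_group")
      }
    }
  }
  groups
}

#' @export
print.charged_group <- function(x, ...) {
  cat(sprintf("<charged_group> %s %s:%d (%s), %d atom(s)\n",
              x$kind, x$chain, x$resno, x$resname, length(x$atom_idx)))
  invisible(x)
}

#' Residence frequency of a charged group near a site
#'
#' Percentage of frames in which the minimum distance between any group
#' atom and any site atom is strictly below `cutoff`. The damaged-site
#' atom set defaults to all heavy atoms of the site residue (backbone and
#' phosphate included); pass explicit `site_idx` for other conventions.
#'
#' @param traj an `ncp_trajectory`.
#' @param group a `charged_group` from [find_charged_groups()], or an
#'   integer vector of atom indices.
#' @param site_idx integer vector of site atom indices (e.g. from
#'   [select_atoms()] with `heavy = TRUE`).
#' @param cutoff contact radius in Angstrom (strict `<`).
#' @return percentage in `[0, 100]` (unrounded).
#' @export
residence_frequency <- function(traj, group, site_idx, cutoff = 6.0) {
  stopifnot(inherits(traj, "ncp_trajectory"))
  g_idx <- if (inherits(group, "charged_group")) group$atom_idx else group
  .require_atoms(g_idx, "charged group atoms")
  .require_atoms(site_idx, "damaged-site atoms")
  if (cutoff <= 0) .stopf("cutoff must be positive")
  hits <- vapply(seq_len(traj$n_frames), function(t) {
    G <- matrix(traj$coords[g_idx, , t], ncol = 3)
    S <- matrix(traj$coords[site_idx, , t], ncol = 3)
    d2 <- outer(rowSums(G^2), rowSums(S^2), "+") - 2 * G %*% t(S)
    min(d2) < cutoff^2
  }, TRUE)
  100 * sum(hits) / traj$n_frames
}

#' Contact residence table over replicates
#'
#' Computes per-replicate residence frequencies for each (group, site)
#' pair and aggregates them with [aggregate_replicates()].
#'
#' @param replicate_trajs named list of `ncp_trajectory` objects (names are
#'   replicate labels, e.g. `"MD1"`).
#' @param pairs list of entries `list(label=, group=, site_idx=)`; `group`
#'   and `site_idx` as in [residence_frequency()]. Atom indices must refer
#'   to the common topology of the replicate trajectories.
#' @param cutoff contact radius in Angstrom.
#' @param decimals table rounding.
#' @return list of `contact_summary` objects (fields `pair_label`,
#'   `summary`).
#' @export
contact_table <- function(replicate_trajs, pairs, cutoff = 6.0,
                          decimals = 1L) {
  stopifnot(length(replicate_trajs) >= 1)
  if (is.null(names(replicate_trajs)))
    names(replicate_trajs) <- paste0("MD", seq_along(replicate_trajs))
  lapply(pairs, function(p) {
    freq <- vapply(replicate_trajs, function(tr)
      residence_frequency(tr, p$group, p$site_idx, cutoff), 0)
    structure(list(pair_label = p$label,
                   summary = aggregate_replicates(freq, decimals)),
              class = "contact_summary")
  })
}

#' @export
print.contact_summary <- function(x, ...) {
  cat(sprintf("%s  ", x$pair_label)); print(x$summary)
  invisible(x)
}
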