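# Structures, trajectories, PDB input/output, atom selections and
# analysis-section extraction.
#
# A structure is a plain list: an atom table plus an n_atoms x 3 coordinate
# matrix (Angstrom). A trajectory holds the topology structure and an
# n_atoms x 3 x n_frames coordinate array. PDB parsing and writing are
# delegated to bio3d; residue numbering follows the PDB file (1-based
# crystallographic numbers) at every interface.

#' Construct a structure object
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resno`, `element`, `mass`, `occupancy`, `bfactor` (and optionally
#'   `pair`, the base-pair index assigned by [build_bdna()]).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param meta optional list of builder metadata (helical rise, twist, ...).
#' @return an object of class `ncp_structure`.
#' @export
ncp_structure <- function(atoms, xyz, meta = NULL) {
  stopifnot(is.data.frame(atoms), is.matrix(xyz), nrow(atoms) == nrow(xyz),
            ncol(xyz) == 3)
  if (!all(is.finite(xyz))) .stopf("non-finite coordinates in structure")
  if (anyDuplicated(atoms$serial)) .stopf("duplicate atom serial numbers")
  structure(list(atoms = atoms, xyz = unname(xyz), meta = meta),
            class = "ncp_structure")
}

#' @export
print.ncp_structure <- function(x, ...) {
  cat(sprintf("<ncp_structure> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")])),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

#' Construct a trajectory object
#'
#' @param topology an `ncp_structure`.
#' @param coords numeric array `n_atoms x 3 x n_frames`.
#' @param frame_stride_ps optional frame spacing metadata (picoseconds).
#' @param states optional ground-truth state table from the synthetic
#'   generator (`frame`, `site`, `state`).
#' @return an object of class `ncp_trajectory`.
#' @export
ncp_trajectory <- function(topology, coords, frame_stride_ps = NULL,
                           states = NULL) {
  stopifnot(inherits(topology, "ncp_structure"))
  if (length(dim(coords)) != 3) .stopf("coords must be a 3-d array")
  if (dim(coords)[1] != nrow(topology$atoms))
    .stopf("coords atom count (%d) does not match topology (%d)",
           dim(coords)[1], nrow(topology$atoms))
  if (dim(coords)[3] < 1) .stopf("trajectory must have at least one frame")
  structure(list(topology = topology, coords = coords,
                 n_frames = dim(coords)[3],
                 frame_stride_ps = frame_stride_ps, states = states),
            class = "ncp_trajectory")
}

#' @export
print.ncp_trajectory <- function(x, ...) {
  cat(sprintf("<ncp_trajectory> %d frames x %d atoms\n",
              x$n_frames, nrow(x$topology$atoms)))
  invisible(x)
}

#' Single-frame view of a trajectory as a structure
#'
#' @param traj an `ncp_trajectory`.
#' @param frame frame number (1-based).
#' @export
frame_structure <- function(traj, frame) {
  stopifnot(inherits(traj, "ncp_trajectory"))
  if (frame < 1 || frame > traj$n_frames)
    .stopf("frame %d out of range (1..%d)", frame, traj$n_frames)
  ncp_structure(traj$topology$atoms, traj$coords[, , frame],
                meta = traj$topology$meta)
}

#' Promote a structure to a one-frame trajectory
#' @param structure an `ncp_structure`.
#' @export
as_trajectory <- function(structure) {
  stopifnot(inherits(structure, "ncp_structure"))
  co <- array(structure$xyz, dim = c(nrow(structure$xyz), 3, 1))
  ncp_trajectory(structure, co)
}

# ---------------------------------------------------------------------------
# PDB reading / writing (bio3d behind the interface)

#' @noRd
.atoms_from_bio3d <- function(pdb) {
  a <- pdb$atom
  el <- trimws(a$elesy)
  blank <- is.na(el) | el == ""
  el[blank] <- .element_from_name(a$elety[blank])
  mass <- element_mass(el, atom_label = sprintf("%s/%s%d", a$elety, a$resid,
                                                a$resno))
  data.frame(serial = a$eleno, name = a$elety, resname = trimws(a$resid),
             chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
             resno = a$resno, element = el, mass = mass,
             occupancy = ifelse(is.na(a$o), 1, a$o),
             bfactor = ifelse(is.na(a$b), 0, a$b),
             stringsAsFactors = FALSE)
}

#' Read a structure from a PDB file
#'
#' Reads the first model of a (possibly multi-model) PDB file. Residue names
#' are preserved verbatim, including abasic-residue names such as `AP` or
#' `THF`; see [lesion_aliases()] for dialect normalization.
#'
#' @param path path to a PDB file.
#' @return an `ncp_structure`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) .stopf("cannot parse PDB file '%s': %s", path,
                               conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    .stopf("cannot parse PDB file '%s': no ATOM records", path)
  atoms <- .atoms_from_bio3d(pdb)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  ncp_structure(atoms, xyz)
}

#' Read a multi-model PDB trajectory
#'
#' Every MODEL in the file must have exactly the atom count of `topology`;
#' a mismatch is reported with the offending model number.
#'
#' @param path path to a multi-model PDB file.
#' @param topology an `ncp_structure` defining the atom order.
#' @return an `ncp_trajectory`.
#' @export
read_trajectory <- function(path, topology) {
  stopifnot(inherits(topology, "ncp_structure"))
  if (!file.exists(path)) .stopf("file not found: %s", path)
  n_top <- nrow(topology$atoms)
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- grepl("^MODEL", lines)
  if (any(model_starts)) {
    model_id <- cumsum(model_starts)
    counts <- tabulate(model_id[is_atom], nbins = max(model_id))
    counts <- counts[counts > 0 | seq_along(counts) <= max(model_id[is_atom])]
    bad <- which(counts != n_top)
    if (length(bad))
      .stopf("model %d has %d atoms but topology has %d",
             bad[1], counts[bad[1]], n_top)
  } else if (sum(is_atom) != n_top) {
    .stopf("model 1 has %d atoms but topology has %d", sum(is_atom), n_top)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) .stopf("cannot parse PDB file '%s': %s", path,
                               conditionMessage(e)))
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  co <- array(NA_real_, dim = c(n_top, 3, n_frames))
  for (f in seq_len(n_frames))
    co[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  ncp_trajectory(topology, co)
}

#' Write a structure (or trajectory) as a (multi-model) PDB file
#'
#' Coordinates are written at the standard PDB precision of 3 decimals.
#'
#' @param x an `ncp_structure` or `ncp_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "ncp_trajectory")) return(write_trajectory(x, path))
  stopifnot(inherits(x, "ncp_structure"))
  a <- x$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(x$xyz)),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain, o = a$occupancy,
                   b = a$bfactor, elesy = a$element)
  invisible(path)
}

#' @export
#' @rdname write_structure
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "ncp_trajectory"))
  a <- x$topology$atoms
  xyz <- t(apply(x$coords, 3, function(fr) as.vector(t(fr))))
  if (x$n_frames == 1) xyz <- matrix(xyz, nrow = 1)
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain, o = a$occupancy,
                   b = a$bfactor, elesy = a$element)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Atom selection

#' Select atoms by chain, residue, atom name or category
#'
#' Returns a deterministic, order-stable set of atom indices (row numbers of
#' the atom table). The `base_only` category excludes the sugar
#' (C1'-C5', O4', O3', O5'), the phosphate (P, OP1, OP2), the abasic O1'
#' pseudo-atom and all hydrogens, leaving the nucleobase heavy atoms;
#' abasic residues therefore yield an empty base-only selection.
#'
#' @param structure an `ncp_structure` (or the topology of a trajectory).
#' @param chain,resno,resname,name optional filters (vectors allowed).
#' @param heavy if `TRUE`, drop hydrogens.
#' @param base_only if `TRUE`, keep nucleobase heavy atoms only.
#' @return integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(structure, chain = NULL, resno = NULL,
                         resname = NULL, name = NULL, heavy = FALSE,
                         base_only = FALSE) {
  stopifnot(inherits(structure, "ncp_structure"))
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (heavy || base_only) keep <- keep & a$element != "H"
  if (base_only) keep <- keep & !(a$name %in% .BACKBONE_ATOMS)
  which(keep)
}

#' @noRd
.require_atoms <- function(idx, what) {
  if (length(idx) == 0) .stopf("empty atom selection: %s", what)
  idx
}

#' Subset a structure or trajectory by atom indices
#' @param x an `ncp_structure` or `ncp_trajectory`.
#' @param idx integer atom indices to keep (in their original order).
#' @export
subset_atoms <- function(x, idx) {
  idx <- sort(unique(idx))
  if (inherits(x, "ncp_structure")) {
    ncp_structure(x$atoms[idx, , drop = FALSE],
                  x$xyz[idx, , drop = FALSE], meta = x$meta)
  } else if (inherits(x, "ncp_trajectory")) {
    top <- subset_atoms(x$topology, idx)
    ncp_trajectory(top, x$coords[idx, , , drop = FALSE],
                   frame_stride_ps = x$frame_stride_ps, states = x$states)
  } else .stopf("subset_atoms: unsupported class")
}

# ---------------------------------------------------------------------------
# Site specification and section extraction

#' Specify a damaged site and its analysis section
#'
#' A site specification names the lesion residue, the residue facing it on
#' the opposite strand, optionally the orphan base and its former
#' Watson-Crick partner, and the residue-number bounds of the analysis
#' section on both strands (typically 15 base pairs around the lesion, of
#' which the central 13 are analyzed).
#'
#' @param lesion,facing,orphan,orphan_partner lists `list(chain=, resno=)`;
#'   `orphan`/`orphan_partner` optional.
#' @param section_i,section_j lists `list(chain=, from=, to=)` giving the
#'   section bounds on the lesion strand and the facing strand.
#' @param label site label, e.g. `"site1"`.
#' @param replicate replicate label, e.g. `"MD1"`.
#' @return an object of class `site_spec`.
#' @export
site_spec <- function(lesion, facing, orphan = NULL, orphan_partner = NULL,
                      section_i, section_j, label = "site",
                      replicate = "MD1") {
  chk <- function(x, nm) {
    if (!is.list(x) || is.null(x$chain) || is.null(x$resno))
      .stopf("%s must be list(chain=, resno=)", nm)
    x
  }
  lesion <- chk(lesion, "lesion"); facing <- chk(facing, "facing")
  if (identical(lesion$chain, facing$chain))
    .stopf("lesion and facing residue must lie on opposite strands")
  sec <- function(x, nm) {
    if (!is.list(x) || is.null(x$chain) || is.null(x$from) || is.null(x$to))
      .stopf("%s must be list(chain=, from=, to=)", nm)
    if (x$from > x$to) .stopf("%s: from > to", nm)
    x
  }
  section_i <- sec(section_i, "section_i")
  section_j <- sec(section_j, "section_j")
  if (lesion$resno < section_i$from || lesion$resno > section_i$to)
    .stopf("lesion residue %d outside section_i [%d, %d]",
           lesion$resno, section_i$from, section_i$to)
  structure(list(lesion = lesion, facing = facing, orphan = orphan,
                 orphan_partner = orphan_partner, section_i = section_i,
                 section_j = section_j, label = label, replicate = replicate),
            class = "site_spec")
}

#' Extract the analysis section around a damaged site
#'
#' Keeps both strands of the section defined in the site specification and
#' removes `trim` base pairs at each extremity of each strand. A 15-bp
#' section with `trim = 1` yields the central 13-bp duplex on which the
#' structural analyses are run; the extra flanking pair in the stored
#' section exists to absorb end fraying.
#'
#' @param x an `ncp_trajectory` or `ncp_structure`.
#' @param spec a [site_spec()].
#' @param trim number of base pairs removed at each end of each strand.
#' @return object of the same class as `x`, restricted to the section.
#' @export
extract_section <- function(x, spec, trim = 0) {
  stopifnot(inherits(spec, "site_spec"))
  if (trim < 0) .stopf("trim must be >= 0")
  len_i <- spec$section_i$to - spec$section_i$from + 1
  len_j <- spec$section_j$to - spec$section_j$from + 1
  if (2 * trim >= min(len_i, len_j))
    .stopf("trim = %d removes the whole %d-bp section", trim, min(len_i, len_j))
  top <- if (inherits(x, "ncp_trajectory")) x$topology else x
  idx_i <- select_atoms(top, chain = spec$section_i$chain,
                        resno = seq(spec$section_i$from + trim,
                                    spec$section_i$to - trim))
  idx_j <- select_atoms(top, chain = spec$section_j$chain,
                        resno = seq(spec$section_j$from + trim,
                                    spec$section_j$to - trim))
  .require_atoms(c(idx_i, idx_j),
                 sprintf("section of site '%s' (check chain/residue bounds)",
                         spec$label))
  subset_atoms(x, c(idx_i, idx_j))
}

#' Residues of a structure, in atom order
#' @param structure an `ncp_structure`.
#' @return data.frame with `chain`, `resno`, `resname`, one row per residue.
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  unique(a[, c("chain", "resno", "resname")])
}
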