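# Synthetic nucleosomal-DNA generator.
#
# Builds canonical B-DNA duplexes from idealized nucleotide geometry,
# introduces AP/THF lesions, bends sections onto circular arcs, and
# simulates trajectories with controllable two-state intra/extrahelical
# flipping, coupled lesion/orphan ejection, scripted histone-tail contact
# episodes and Gaussian coordinate noise. This is a geometry and kinetics
# emulator with known ground truth, not a physical model: no force field,
# no solvent, no thermodynamics.

.WC_COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

# Watson-Crick pair frame. The helix axis is z through the origin; the
# pair long axis is y. C1' of strand I sits at the standard-frame position
# below; the glycosidic bond makes a 54.5 degree angle with the C1'-C1'
# line. The strand II nucleotide is the complementary template rotated 180
# degrees about x (a proper rotation; chirality is preserved).
.C1_I <- c(-2.477, 5.399, 0)
.GLYC_BOND <- 1.47
.GLYC_LAMBDA <- 54.5
.HBOND_CENTRAL <- 2.82

#' @noRd
.glyc_target <- function() {
  .C1_I + .GLYC_BOND * c(sin(.deg2rad(.GLYC_LAMBDA)),
                         -cos(.deg2rad(.GLYC_LAMBDA)), 0)
}

#' @noRd
.glyc_atom <- function(res) if (res %in% c("DA", "DG")) "N9" else "N1"

#' @noRd
.wc_atom <- function(res) if (res %in% c("DA", "DG")) "N1" else "N3"

# Place the two nucleotides of a pair in the pair frame. Solves the
# in-plane orientation of each base so that the central Watson-Crick
# hydrogen bond (purine N1 to pyrimidine N3) has the canonical length and
# runs parallel to the pair long axis, then rigidly fits the idealized
# 3-d nucleotide onto the three anchor atoms.
#' @noRd
.place_pair <- function(resI, resJ) {
  g <- .glyc_target()
  A <- .residue_template(resI); B <- .residue_template(resJ)
  lA <- .vnorm(A[.wc_atom(resI), ] - A[.glyc_atom(resI), ])
  lB <- .vnorm(B[.wc_atom(resJ), ] - B[.glyc_atom(resJ), ])
  S <- .HBOND_CENTRAL - 2 * g[2]
  D <- (lA^2 - lB^2) / S
  u <- (S + D) / 2
  v <- (S - D) / 2
  xw <- g[1] + sqrt(lA^2 - u^2)
  wA <- c(xw, g[2] + u, 0)
  wB <- c(xw, g[2] + v, 0)
  fit <- function(X, res, wt) {
    P <- rbind(X["C1'", ], X[.glyc_atom(res), ], X[.wc_atom(res), ])
    Q <- rbind(.C1_I, g, wt)
    Y <- .apply_rt(X, .kabsch_rt(P, Q))
    dimnames(Y) <- dimnames(X)
    attr(Y, "element") <- attr(X, "element")
    Y
  }
  I <- fit(A, resI, wA)
  J0 <- fit(B, resJ, wB)
  J <- J0 %*% diag(c(1, -1, -1))
  dimnames(J) <- dimnames(J0)
  attr(J, "element") <- attr(J0, "element")
  list(I = I, J = J)
}

#' Configuration of the synthetic duplex generator
#'
#' @param sequence 5'-to-3' sequence of strand I over `A`, `C`, `G`, `T`.
#' @param lesion_position residue number (strand I numbering, 1-based) at
#'   which to place the lesion, or `NULL` for an undamaged duplex.
#' @param lesion_type `"AP"` or `"THF"`.
#' @param orphan_position optional residue number of the orphan base on the
#'   facing strand (duplex numbering, see [build_bdna()]).
#' @param helical_rise axial rise per base pair in Angstrom.
#' @param helical_twist twist per base pair in degrees.
#' @param noise_sigma per-coordinate Gaussian noise (Angstrom) for
#'   trajectory generation.
#' @param seed integer seed fixing all stochastic output.
#' @param n_frames number of trajectory frames to generate.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(sequence, lesion_position = NULL,
                         lesion_type = c("AP", "THF"),
                         orphan_position = NULL, helical_rise = 3.38,
                         helical_twist = 36.0, noise_sigma = 0,
                         seed = 1L, n_frames = 1L) {
  lesion_type <- match.arg(lesion_type)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1) .stopf("sequence must be non-empty")
  if (grepl("[^ACGT]", sequence))
    .stopf("sequence contains non-ACGT characters: %s", sequence)
  if (noise_sigma < 0) .stopf("noise_sigma must be >= 0")
  structure(list(sequence = sequence, lesion_position = lesion_position,
                 lesion_type = lesion_type,
                 orphan_position = orphan_position,
                 helical_rise = helical_rise, helical_twist = helical_twist,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 n_frames = as.integer(n_frames)),
            class = "synth_config")
}

#' Sequence helper: alternating dA-dT / dC-dG tetramer blocks
#'
#' @param n_bp desired duplex length in base pairs.
#' @param start `"AT"` or `"GC"`, which tetramer type leads.
#' @return a strand-I sequence string of length `n_bp`.
#' @export
tetramer_sequence <- function(n_bp, start = c("AT", "GC")) {
  start <- match.arg(start)
  blocks <- if (start == "AT") c("ATAT", "GCGC") else c("GCGC", "ATAT")
  s <- paste(rep(blocks, length.out = ceiling(n_bp / 4)), collapse = "")
  substr(s, 1, n_bp)
}

#' Build a canonical B-DNA duplex
#'
#' Strand I carries the given sequence 5'-to-3' as chain `"I"`, residues
#' `1..n`; the Watson-Crick complement is chain `"J"`, residues `n+1..2n`
#' in its own 5'-to-3' order, so that residue `i` pairs with residue
#' `2n+1-i` (the numbering convention of nucleosomal crystal structures).
#' Successive base pairs are related by `helical_rise` along the helix
#' axis and `helical_twist` about it. The output is deterministic.
#'
#' @param config a [synth_config()], or a character sequence (in which case
#'   the remaining defaults are used).
#' @return an `ncp_structure` with base-pair indices in `atoms$pair` and
#'   builder metadata in `$meta`.
#' @export
build_bdna <- function(config) {
  if (is.character(config)) config <- synth_config(config)
  stopifnot(inherits(config, "synth_config"))
  bases <- strsplit(config$sequence, "")[[1]]
  n <- length(bases)
  rows <- list(); coords <- list(); pairJ <- list()
  for (i in seq_len(n)) {
    pr <- .place_pair(paste0("D", bases[i]),
                      paste0("D", .WC_COMPLEMENT[bases[i]]))
    Rz <- .rotz((i - 1) * config$helical_twist)
    shift <- c(0, 0, (i - 1) * config$helical_rise)
    pr$I <- sweep(pr$I %*% t(Rz), 2, shift, "+")
    pr$J <- sweep(pr$J %*% t(Rz), 2, shift, "+")
    elI <- attr(.residue_template(paste0("D", bases[i])), "element")
    elJ <- attr(.residue_template(paste0("D", .WC_COMPLEMENT[bases[i]])),
                "element")
    rows[[i]] <- data.frame(
      name = rownames(pr$I), resname = paste0("D", bases[i]),
      chain = "I", resno = i, element = unname(elI[rownames(pr$I)]),
      pair = i, stringsAsFactors = FALSE)
    coords[[i]] <- pr$I
    pairJ[[i]] <- list(
      atoms = data.frame(
        name = rownames(pr$J),
        resname = paste0("D", .WC_COMPLEMENT[bases[i]]),
        chain = "J", resno = 2 * n + 1 - i,
        element = unname(elJ[rownames(pr$J)]),
        pair = i, stringsAsFactors = FALSE),
      xyz = pr$J)
  }
  # strand J in ascending residue-number (5'->3') order: pair n down to 1
  for (i in rev(seq_len(n))) {
    rows[[length(rows) + 1]] <- pairJ[[i]]$atoms
    coords[[length(coords) + 1]] <- pairJ[[i]]$xyz
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$mass <- element_mass(atoms$element, atoms$name)
  atoms$occupancy <- 1; atoms$bfactor <- 0
  atoms <- atoms[, c("serial", "name", "resname", "chain", "resno",
                     "element", "mass", "occupancy", "bfactor", "pair")]
  xyz <- do.call(rbind, coords)
  st <- ncp_structure(atoms, xyz,
                      meta = list(n_bp = n, rise = config$helical_rise,
                                  twist = config$helical_twist,
                                  sequence = config$sequence))
  if (!is.null(config$lesion_position))
    st <- apply_lesion(st, config$lesion_position, config$lesion_type)
  st
}

#' Replace a nucleotide by an abasic site
#'
#' Removes the nucleobase heavy atoms, retains sugar and backbone, and
#' renames the residue. For an `AP` (deoxyribo-type) lesion an `O1'`
#' hydroxyl pseudo-atom is placed along the former glycosidic bond vector;
#' the `THF` analog lacks this oxygen function, which is the entire
#' structural difference between the two lesion types here.
#'
#' @param structure an `ncp_structure`.
#' @param resno residue number of the nucleotide to convert.
#' @param lesion_type `"AP"` or `"THF"`.
#' @param chain chain of the residue (default `"I"`).
#' @return the modified `ncp_structure` (serials renumbered).
#' @export
apply_lesion <- function(structure, resno, lesion_type = c("AP", "THF"),
                         chain = "I") {
  lesion_type <- match.arg(lesion_type)
  stopifnot(inherits(structure, "ncp_structure"))
  res_idx <- select_atoms(structure, chain = chain, resno = resno)
  .require_atoms(res_idx, sprintf("residue %s:%d", chain, resno))
  resname <- structure$atoms$resname[res_idx[1]]
  if (is_abasic(resname))
    .stopf("residue %s:%d is already abasic (%s)", chain, resno, resname)
  base_idx <- select_atoms(structure, chain = chain, resno = resno,
                           base_only = TRUE)
  if (length(base_idx) == 0)
    .stopf("residue %s:%d (%s) has no nucleobase to remove",
           chain, resno, resname)
  c1_idx <- select_atoms(structure, chain = chain, resno = resno,
                         name = "C1'")
  .require_atoms(c1_idx, sprintf("C1' of residue %s:%d", chain, resno))
  glyc <- .glyc_atom(resname)
  g_idx <- select_atoms(structure, chain = chain, resno = resno, name = glyc)
  atoms <- structure$atoms
  xyz <- structure$xyz
  add <- NULL; add_xyz <- NULL
  if (lesion_type == "AP") {
    if (length(g_idx) == 1) {
      dirv <- xyz[g_idx, ] - xyz[c1_idx, ]
      dirv <- dirv / .vnorm(dirv)
    } else {
      dirv <- c(0, 0, 1)
    }
    tmpl <- atoms[c1_idx, ]
    tmpl$name <- "O1'"; tmpl$element <- "O"
    tmpl$mass <- element_mass("O")
    add <- tmpl
    add_xyz <- matrix(xyz[c1_idx, ] + 1.43 * dirv, 1, 3)
  }
  keep <- setdiff(seq_len(nrow(atoms)), base_idx)
  atoms2 <- atoms[keep, , drop = FALSE]
  xyz2 <- xyz[keep, , drop = FALSE]
  if (!is.null(add)) {
    pos <- which(atoms2$chain == chain & atoms2$resno == resno &
                   atoms2$name == "C1'")
    atoms2 <- rbind(atoms2[seq_len(pos), ], add,
                    if (pos < nrow(atoms2))
                      atoms2[(pos + 1):nrow(atoms2), ])
    xyz2 <- rbind(xyz2[seq_len(pos), , drop = FALSE], add_xyz,
                  if (pos < nrow(xyz2)) xyz2[(pos + 1):nrow(xyz2), ,
                                             drop = FALSE])
  }
  atoms2$resname[atoms2$chain == chain & atoms2$resno == resno] <- lesion_type
  atoms2$serial <- seq_len(nrow(atoms2))
  rownames(atoms2) <- NULL
  ncp_structure(atoms2, xyz2, meta = structure$meta)
}

#' Bend a built duplex onto a circular arc
#'
#' Maps the helix axis onto a planar circular arc whose end-tangent angle
#' equals `angle`; every base pair is transported rigidly (internal pair
#' geometry is preserved exactly). `angle = 0` returns the input
#' coordinates unchanged. Requires builder metadata (`atoms$pair`), i.e. a
#' structure from [build_bdna()] / [apply_lesion()].
#'
#' @param structure an `ncp_structure` from the builder.
#' @param angle arc end-tangent angle in degrees, `0 <= angle < 180`.
#' @return the bent `ncp_structure`.
#' @export
bend_arc <- function(structure, angle) {
  stopifnot(inherits(structure, "ncp_structure"))
  if (angle < 0 || angle >= 180)
    .stopf("bend angle must be in [0, 180), got %g", angle)
  if (is.null(structure$atoms$pair) || all(is.na(structure$atoms$pair)))
    .stopf("bend_arc requires a built duplex with base-pair metadata")
  if (angle == 0) return(structure)
  meta <- structure$meta
  if (is.null(meta$rise) || is.null(meta$n_bp))
    .stopf("bend_arc requires builder metadata (rise, n_bp)")
  n <- meta$n_bp; ds <- meta$rise
  L <- (n - 1) * ds
  kap <- .deg2rad(angle) / L
  R <- 1 / kap
  xyz <- structure$xyz
  for (i in seq_len(n)) {
    idx <- which(structure$atoms$pair == i)
    if (length(idx) == 0) next
    s <- (i - 1) * ds
    phi <- s * kap
    Ry <- matrix(c(cos(phi), 0, -sin(phi),
                   0, 1, 0,
                   sin(phi), 0, cos(phi)), 3, 3, byrow = TRUE)
    Q <- c(R * (1 - cos(phi)), 0, R * sin(phi))
    xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, c(0, 0, s)) %*%
                          t(Ry), 2, Q, "+")
  }
  out <- structure
  out$xyz <- xyz
  out$meta$bend_angle <- angle
  out
}

# ---------------------------------------------------------------------------
# Two-state flipping kinetics

#' Specify the flipping kinetics of one site
#'
#' In `markov` mode the site follows a first-order two-state chain with
#' per-frame switching probabilities `p_out` (intra to extra) and `p_in`
#' (extra to intra); the stationary extrahelical occupancy is
#' `p_out / (p_out + p_in)`. In `exact_fraction` mode exactly
#' `round(fraction * n_frames)` frames are extrahelical, placed evenly
#' spaced (deterministically, and non-contiguously whenever the fraction
#' permits) -- occupancy is a percentage of time, not a consecutive block.
#' A site with `couple_to` set follows the hidden state sequence of the
#' named site, with independent per-frame emission errors
#' (`emission_error`) -- the inchworm coupling of lesion and orphan base.
#'
#' @param resno residue number of the flipping residue.
#' @param chain its chain.
#' @param name site name used in ground-truth tables and coupling
#'   references; defaults to `"<chain>:<resno>"`.
#' @param mode `"markov"` or `"exact_fraction"`.
#' @param p_out,p_in markov-mode switching probabilities in `[0, 1]`.
#' @param fraction exact-fraction-mode extrahelical occupancy in `[0, 1]`.
#' @param couple_to name of the driving site, or `NULL`.
#' @param emission_error per-frame probability that a coupled site deviates
#'   from its driver.
#' @param flip_angle rotation (degrees) of the residue about the axis
#'   through its flanking backbone phosphates used to construct the
#'   extrahelical conformer.
#' @param out_shift additional rigid displacement (Angstrom) of the flipped
#'   residue directly away from its facing residue's C1', which guarantees
#'   that the extrahelical template crosses the classification thresholds
#'   with a clear margin.
#' @return an object of class `flip_spec`.
#' @export
flip_spec <- function(resno, chain = "I", name = NULL,
                      mode = c("markov", "exact_fraction"),
                      p_out = NULL, p_in = NULL, fraction = NULL,
                      couple_to = NULL, emission_error = 0.02,
                      flip_angle = 110, out_shift = 3.5) {
  mode <- match.arg(mode)
  if (is.null(name)) name <- sprintf("%s:%d", chain, resno)
  if (is.null(couple_to)) {
    if (mode == "markov") {
      if (is.null(p_out) || is.null(p_in))
        .stopf("markov mode requires p_out and p_in (site %s)", name)
      if (p_out < 0 || p_out > 1 || p_in < 0 || p_in > 1)
        .stopf("switching probabilities must lie in [0, 1] (site %s)", name)
    } else {
      if (is.null(fraction))
        .stopf("exact_fraction mode requires a fraction (site %s)", name)
      if (fraction < 0 || fraction > 1)
        .stopf("fraction must lie in [0, 1] (site %s)", name)
    }
  }
  structure(list(resno = resno, chain = chain, name = name, mode = mode,
                 p_out = p_out, p_in = p_in, fraction = fraction,
                 couple_to = couple_to, emission_error = emission_error,
                 flip_angle = flip_angle, out_shift = out_shift),
            class = "flip_spec")
}

# Evenly spaced placement of `count` marked frames among `n`.
#' @noRd
.even_placement <- function(n, count) {
  if (count <= 0) return(logical(n))
  i <- seq_len(n)
  (i * count) %/% n > ((i - 1) * count) %/% n
}

#' Simulate per-frame intra/extrahelical state sequences
#'
#' Ground-truth state generation, independent of any coordinates: useful
#' for validating occupancy statistics at large frame counts. All
#' randomness is governed by `seed`.
#'
#' @param flips list of [flip_spec()] objects.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return logical matrix `n_frames x length(flips)` (TRUE = extrahelical),
#'   with site names as column names.
#' @export
simulate_flip_states <- function(flips, n_frames, seed = 1L) {
  if (inherits(flips, "flip_spec")) flips <- list(flips)
  stopifnot(all(vapply(flips, inherits, TRUE, "flip_spec")), n_frames >= 1)
  nms <- vapply(flips, function(f) f$name, "")
  if (anyDuplicated(nms)) .stopf("duplicate flip site names")
  set.seed(as.integer(seed))
  out <- matrix(FALSE, n_frames, length(flips), dimnames = list(NULL, nms))
  # drivers first, coupled sites second
  is_coupled <- !vapply(flips, function(f) is.null(f$couple_to), TRUE)
  for (k in which(!is_coupled)) {
    f <- flips[[k]]
    if (f$mode == "exact_fraction") {
      count <- round(f$fraction * n_frames)
      out[, k] <- .even_placement(n_frames, count)
    } else {
      s <- logical(n_frames)
      cur <- FALSE   # start intrahelical
      u <- stats::runif(n_frames)
      for (t in seq_len(n_frames)) {
        cur <- if (cur) u[t] >= f$p_in else u[t] < f$p_out
        s[t] <- cur
      }
      out[, k] <- s
    }
  }
  for (k in which(is_coupled)) {
    f <- flips[[k]]
    j <- match(f$couple_to, nms)
    if (is.na(j)) .stopf("coupling references unknown site '%s'", f$couple_to)
    if (!is.null(flips[[j]]$couple_to))
      .stopf("site '%s' couples to a site that is itself coupled", f$name)
    err <- stats::runif(n_frames) < f$emission_error
    out[, k] <- xor(out[, j], err)
  }
  out
}

# Extrahelical conformer of one residue: rotation about the flanking
# phosphate axis plus a rigid displacement away from the facing C1'.
#' @noRd
.extra_conformer <- function(structure, f) {
  a <- structure$atoms
  res_idx <- select_atoms(structure, chain = f$chain, resno = f$resno)
  .require_atoms(res_idx, sprintf("flip site %s", f$name))
  own_p <- select_atoms(structure, chain = f$chain, resno = f$resno,
                        name = "P")
  nb <- c(f$resno + 1, f$resno - 1)
  nb_p <- integer(0)
  for (r in nb) {
    nb_p <- select_atoms(structure, chain = f$chain, resno = r, name = "P")
    if (length(nb_p) == 1) break
  }
  if (length(own_p) != 1 || length(nb_p) != 1)
    .stopf("flip site %s needs its own and a neighbouring backbone P atom",
           f$name)
  pair_id <- a$pair[res_idx[1]]
  if (is.null(pair_id) || is.na(pair_id))
    .stopf("flip conformers require a built duplex (site %s)", f$name)
  facing_c1 <- which(a$pair == pair_id & a$chain != f$chain & a$name == "C1'")
  .require_atoms(facing_c1, sprintf("facing C1' of site %s", f$name))
  xyz <- structure$xyz
  rot <- .rotate_about_line(xyz[res_idx, , drop = FALSE],
                            xyz[own_p, ], xyz[nb_p, ], f$flip_angle)
  c1_row <- which(a$name[res_idx] == "C1'")
  dirv <- rot[c1_row, ] - xyz[facing_c1, ]
  dirv <- dirv / .vnorm(dirv)
  rot <- sweep(rot, 2, f$out_shift * dirv, "+")
  list(idx = res_idx, coords = rot)
}

#' Simulate a flipping trajectory
#'
#' Generates `n_frames` coordinate frames of the given duplex in which each
#' flip site alternates between its built (intrahelical) conformation and
#' an extrahelical conformer, according to [simulate_flip_states()], with
#' optional Gaussian coordinate noise. The ground-truth state table is
#' stored in the returned trajectory's `$states`.
#'
#' @param structure a built (possibly lesioned / bent) duplex.
#' @param flips list of [flip_spec()] objects.
#' @param n_frames number of frames.
#' @param seed integer seed (fixes states and noise bit-for-bit).
#' @param noise_sigma per-coordinate Gaussian noise (Angstrom).
#' @return an `ncp_trajectory` with `$states` (data.frame: `frame`, `site`,
#'   `state`).
#' @export
simulate_flip_dynamics <- function(structure, flips, n_frames, seed = 1L,
                                   noise_sigma = 0) {
  stopifnot(inherits(structure, "ncp_structure"))
  if (inherits(flips, "flip_spec")) flips <- list(flips)
  if (noise_sigma < 0) .stopf("noise_sigma must be >= 0")
  conf <- lapply(flips, function(f) .extra_conformer(structure, f))
  states <- simulate_flip_states(flips, n_frames, seed = seed)
  n_atoms <- nrow(structure$atoms)
  co <- array(rep(structure$xyz, n_frames), dim = c(n_atoms, 3, n_frames))
  for (k in seq_along(flips)) {
    fr_extra <- which(states[, k])
    for (t in fr_extra) co[conf[[k]]$idx, , t] <- conf[[k]]$coords
  }
  if (noise_sigma > 0)
    co <- co + array(stats::rnorm(length(co), 0, noise_sigma), dim = dim(co))
  st_long <- data.frame(
    frame = rep(seq_len(n_frames), times = ncol(states)),
    site = rep(colnames(states), each = n_frames),
    state = ifelse(as.vector(states), "extra", "intra"),
    stringsAsFactors = FALSE)
  tr <- ncp_trajectory(structure, co, states = st_long)
  attr(tr$states, "wide") <- states
  tr
}

#' Write the ground-truth state table of a synthetic trajectory
#' @param traj trajectory from [simulate_flip_dynamics()].
#' @param path CSV output path.
#' @export
write_ground_truth <- function(traj, path) {
  if (is.null(traj$states)) .stopf("trajectory carries no ground-truth states")
  utils::write.csv(traj$states, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Scripted histone-tail contact probe

#' Script contact episodes of a charged tail probe
#'
#' @param episodes data.frame with columns `start`, `end` (frame numbers,
#'   1-based, inclusive) and `target_distance` (Angstrom). Episodes must
#'   not overlap.
#' @param off_distance probe distance from the site outside episodes.
#' @param kind `"LYS_NZ"` (a lysine-like bead with atoms N, CA, NZ) or
#'   `"NTERM_N"` (a single backbone-amine bead).
#' @return an object of class `contact_script`.
#' @export
contact_script <- function(episodes, off_distance = 20,
                           kind = c("LYS_NZ", "NTERM_N")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(episodes),
            all(c("start", "end", "target_distance") %in% names(episodes)))
  if (nrow(episodes)) {
    if (any(episodes$start > episodes$end)) .stopf("episode start > end")
    if (any(episodes$start < 1)) .stopf("episode starts before frame 1")
    o <- order(episodes$start)
    ep <- episodes[o, ]
    if (nrow(ep) > 1 && any(ep$start[-1] <= ep$end[-nrow(ep)]))
      .stopf("contact episodes overlap")
    if (any(episodes$target_distance >= off_distance))
      .stopf("target_distance must be smaller than off_distance")
  }
  structure(list(episodes = episodes, off_distance = off_distance,
                 kind = kind), class = "contact_script")
}

#' Add a scripted charged-group probe to a trajectory
#'
#' Appends a probe residue (chain `"P"`) whose charged atom (`NZ` for a
#' lysine-like probe, `N` for an N-terminal amine) sits at exactly
#' `target_distance` from the nearest heavy atom of the damaged site
#' during each episode and at `off_distance` otherwise. The probe
#' approaches along a fixed outward direction, so the scripted distance is
#' exactly the minimum probe-to-site distance.
#'
#' @param traj an `ncp_trajectory`.
#' @param script a [contact_script()].
#' @param site_resno,site_chain residue defining the damaged site.
#' @param resno residue number given to the probe.
#' @return a new `ncp_trajectory` including the probe atoms.
#' @export
add_tail_probe <- function(traj, script, site_resno, site_chain = "I",
                           resno = 13L) {
  stopifnot(inherits(traj, "ncp_trajectory"),
            inherits(script, "contact_script"))
  if (nrow(script$episodes) && any(script$episodes$end > traj$n_frames))
    .stopf("contact episode extends past the last frame (%d)", traj$n_frames)
  top <- traj$topology
  site_idx <- select_atoms(top, chain = site_chain, resno = site_resno,
                           heavy = TRUE)
  .require_atoms(site_idx, sprintf("damaged site %s:%d", site_chain,
                                   site_resno))
  # fixed outward approach direction from the global centroid through the
  # site centroid (frame 1); falls back to +x for degenerate geometry
  cen_all <- colMeans(traj$coords[, , 1])
  cen_site <- colMeans(traj$coords[site_idx, , 1, drop = FALSE][, , 1,
                                                                drop = FALSE])
  dirv <- cen_site - cen_all
  if (.vnorm(dirv) < 1e-8) dirv <- c(1, 0, 0)
  dirv <- dirv / .vnorm(dirv)
  atom_names <- if (script$kind == "LYS_NZ") c("NZ", "CA", "N") else "N"
  offsets <- if (script$kind == "LYS_NZ") c(0, 1.5, 3.0) else 0
  n_new <- length(atom_names)
  probe_atoms <- data.frame(
    serial = max(top$atoms$serial) + seq_len(n_new),
    name = atom_names,
    resname = if (script$kind == "LYS_NZ") "LYS" else "GLY",
    chain = "P", resno = resno, element = substr(atom_names, 1, 1),
    mass = element_mass(substr(atom_names, 1, 1)),
    occupancy = 1, bfactor = 0, stringsAsFactors = FALSE)
  if (!is.null(top$atoms$pair)) probe_atoms$pair <- NA_integer_
  new_atoms <- rbind(top$atoms, probe_atoms)
  new_top <- ncp_structure(new_atoms,
                           rbind(top$xyz, matrix(0, n_new, 3)),
                           meta = top$meta)
  dist_per_frame <- rep(script$off_distance, traj$n_frames)
  if (nrow(script$episodes))
    for (e in seq_len(nrow(script$episodes)))
      dist_per_frame[script$episodes$start[e]:script$episodes$end[e]] <-
        script$episodes$target_distance[e]
  co <- array(NA_real_, dim = c(nrow(new_atoms), 3, traj$n_frames))
  co[seq_len(nrow(top$atoms)), , ] <- traj$coords
  for (t in seq_len(traj$n_frames)) {
    site_xyz <- traj$coords[site_idx, , t, drop = FALSE][, , 1, drop = FALSE]
    site_xyz <- matrix(site_xyz, ncol = 3)
    proj <- site_xyz %*% dirv
    anchor <- site_xyz[which.max(proj), ]
    for (j in seq_len(n_new))
      co[nrow(top$atoms) + j, , t] <-
        anchor + (dist_per_frame[t] + offsets[j]) * dirv
  }
  contact_truth <- dist_per_frame < script$off_distance
  tr <- ncp_trajectory(new_top, co, frame_stride_ps = traj$frame_stride_ps,
                       states = traj$states)
  attr(tr, "contact_frames") <- contact_truth
  tr
}

#' Build a short histone-tail-like peptide
#'
#' Places idealized residues along a line (no physical backbone geometry;
#' intended for charged-group detection and contact fixtures).
#'
#' @param residues character vector of 3-letter residue names (templates
#'   exist for ALA, GLY, LYS, ARG).
#' @param chain chain identifier.
#' @param start_resno residue number of the first (N-terminal) residue.
#' @param origin coordinates of the first residue's anchor.
#' @param spacing translation between consecutive residues (Angstrom).
#' @param direction unit direction of the chain.
#' @return an `ncp_structure`.
#' @export
build_tail <- function(residues, chain = "H", start_resno = 1L,
                       origin = c(0, 0, 0), spacing = 3.8,
                       direction = c(1, 0, 0)) {
  direction <- direction / .vnorm(direction)
  rows <- list(); coords <- list()
  for (k in seq_along(residues)) {
    tm <- .residue_template(residues[k])
    el <- attr(tm, "element")
    shift <- origin + (k - 1) * spacing * direction - colMeans(tm)
    rows[[k]] <- data.frame(
      name = rownames(tm), resname = residues[k], chain = chain,
      resno = start_resno + k - 1, element = unname(el[rownames(tm)]),
      stringsAsFactors = FALSE)
    coords[[k]] <- sweep(tm, 2, -shift)
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$mass <- element_mass(atoms$element, atoms$name)
  atoms$occupancy <- 1; atoms$bfactor <- 0
  atoms <- atoms[, c("serial", "name", "resname", "chain", "resno",
                     "element", "mass", "occupancy", "bfactor")]
  ncp_structure(atoms, do.call(rbind, coords))
}
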