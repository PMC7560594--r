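# Atomic masses, residue alias tables and idealized residue templates.

# Standard atomic masses (amu). Unknown elements are a hard error so that
# center-of-mass computations can never silently fall back to unit masses.
.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  K = 39.098, NA. = 22.990, CL = 35.45, MG = 24.305, MN = 54.938,
  ZN = 65.38, FE = 55.845
)

#' Look up atomic masses by element symbol
#'
#' @param element character vector of element symbols (e.g. `"C"`, `"P"`).
#' @param atom_label optional labels (atom names) used in error messages.
#' @return numeric vector of masses in amu.
#' @export
element_mass <- function(element, atom_label = element) {
  el <- toupper(trimws(element))
  el[el == "NA"] <- "NA."
  m <- .ATOMIC_MASS[el]
  if (anyNA(m)) {
    bad <- unique(atom_label[is.na(m)])
    .stopf("unknown element(s), cannot assign mass: %s",
           paste(bad, collapse = ", "))
  }
  unname(m)
}

# Infer element symbol from a PDB atom name when the element column is blank.
#' @noRd
.element_from_name <- function(name) {
  nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", trimws(name)))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "MG", "MN", "ZN", "FE", "NA"), two, one)
}

#' Abasic-residue alias table
#'
#' Force-field and PDB dialects name abasic residues differently. The alias
#' table maps the common spellings onto the two canonical lesion names used
#' throughout this package: `"AP"` (deoxyribo-type abasic site, with the
#' anomeric hydroxyl) and `"THF"` (the tetrahydrofuran analog, without it).
#'
#' @return named character vector mapping residue-name aliases to `AP`/`THF`.
#' @export
lesion_aliases <- function() {
  c(AP = "AP", AB = "AP", "3DR" = "AP",
    THF = "THF", F = "THF", ORP = "THF")
}

#' Canonicalize a lesion residue name
#'
#' @param resname character vector of residue names.
#' @param aliases alias table, by default [lesion_aliases()].
#' @return canonical lesion name (`"AP"`/`"THF"`) or `NA` for non-lesions.
#' @export
canonical_lesion <- function(resname, aliases = lesion_aliases()) {
  unname(aliases[toupper(resname)])
}

#' @export
#' @rdname canonical_lesion
is_abasic <- function(resname, aliases = lesion_aliases()) {
  !is.na(canonical_lesion(resname, aliases))
}

# Sugar + phosphate atom names of a deoxyribonucleotide. "Base-only"
# selections are the complement of this set among heavy atoms.
.BACKBONE_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "C5'",
                     "O4'", "O3'", "O5'", "P", "OP1", "OP2", "O1'")

# Default atom subset of the orphan-base ejection descriptor: nucleobase
# heavy atoms plus the two sugar atoms at the base attachment. See the
# methods vignette for the calibration of this choice against the 6.8 A
# canonical-pair reference.
.BASE_EXT_KEEP <- c("C1'", "C2'")

# Idealized heavy-atom residue geometries (DA/DT/DG/DC, LYS/ARG/ALA/GLY),
# bundled as plain text. Cached per session.
.template_env <- new.env(parent = emptyenv())

#' @noRd
.residue_template <- function(res) {
  if (is.null(.template_env$tab)) {
    path <- system.file("extdata", "ideal_residues.csv", package = "ncptraj",
                        mustWork = TRUE)
    .template_env$tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  tab <- .template_env$tab
  d <- tab[tab$res == res, ]
  if (nrow(d) == 0) .stopf("no idealized template for residue '%s'", res)
  xyz <- as.matrix(d[, c("x", "y", "z")])
  dimnames(xyz) <- list(d$name, NULL)
  attr(xyz, "element") <- stats::setNames(d$element, d$name)
  xyz
}
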