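# Atomic models: PDB I/O through bio3d, plus the per-atom parameters
# (element radii, atomic numbers, side-chain formal charges) used by the
# density simulation and the interface energy function.

ELEMENT_PARAMS <- data.frame(
  element = c("H", "C", "N", "O", "S", "P"),
  z       = c(1, 6, 7, 8, 16, 15),
  radius  = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80),
  stringsAsFactors = FALSE
)
DEFAULT_RADIUS <- 1.70
DEFAULT_Z <- 6

# Formal side-chain charges by (residue, atom name); spread over the
# equivalent terminal atoms of carboxylates and the guanidinium group.
CHARGE_TABLE <- data.frame(
  resid = c("LYS", "ARG", "ARG", "ARG", "ASP", "ASP", "GLU", "GLU"),
  atom  = c("NZ", "NE", "NH1", "NH2", "OD1", "OD2", "OE1", "OE2"),
  charge = c(1, 1 / 3, 1 / 3, 1 / 3, -0.5, -0.5, -0.5, -0.5),
  stringsAsFactors = FALSE
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

element_from_name <- function(elety, elesy = NULL) {
  el <- toupper(ifelse(is.null(elesy) | is.na(elesy) | elesy == "",
                       NA_character_, elesy))
  guess <- toupper(substr(gsub("^[0-9]+", "", elety), 1, 1))
  out <- ifelse(is.na(el), guess, el)
  out
}

lookup_element <- function(element, column) {
  i <- match(element, ELEMENT_PARAMS$element)
  vals <- ELEMENT_PARAMS[[column]][i]
  default <- if (column == "z") DEFAULT_Z else DEFAULT_RADIUS
  ifelse(is.na(vals), default, vals)
}

lookup_charge <- function(resid, atom) {
  key <- paste(resid, atom)
  i <- match(key, paste(CHARGE_TABLE$resid, CHARGE_TABLE$atom))
  ifelse(is.na(i), 0, CHARGE_TABLE$charge[i])
}

#' Construct an atomic model
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `atom`
#'   (atom name), `element`, `x`, `y`, `z`, and optionally `charge`
#'   (electron units) and `radius` (Angstrom); missing parameters are filled
#'   from the packaged element/residue tables.
#' @param receptor_chains,ligand_chains chain identifiers partitioning the
#'   model into the receptor and ligand sides of the interface.
#' @return an `atomic_model`.
#' @export
atomic_model <- function(atoms, receptor_chains, ligand_chains) {
  need <- c("chain", "resno", "resid", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("`atoms` must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  unknown <- setdiff(unique(atoms$element), ELEMENT_PARAMS$element)
  if (length(unknown))
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; using default radius/atomic number")
  if (is.null(atoms$charge)) atoms$charge <- lookup_charge(atoms$resid, atoms$atom)
  if (is.null(atoms$radius)) atoms$radius <- lookup_element(atoms$element, "radius")
  atoms$z_number <- lookup_element(atoms$element, "z")
  if (any(atoms$radius <= 0)) stop("atom radii must be > 0")
  both <- intersect(receptor_chains, ligand_chains)
  if (length(both))
    stop("chains cannot be both receptor and ligand: ", paste(both, collapse = ","))
  dup <- duplicated(atoms[, c("chain", "resno", "atom")])
  if (any(dup))
    stop("duplicate (chain, residue, atom) records at rows ",
         paste(which(dup), collapse = ","))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 receptor_chains = receptor_chains,
                 ligand_chains = ligand_chains),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf(
    "<atomic_model> %d atoms, %d residues; receptor chains {%s}, ligand chains {%s}\n",
    nrow(x$atoms),
    nrow(unique(x$atoms[, c("chain", "resno")])),
    paste(x$receptor_chains, collapse = ","),
    paste(x$ligand_chains, collapse = ",")))
  invisible(x)
}

atom_coords <- function(model, sel = TRUE) {
  as.matrix(model$atoms[sel, c("x", "y", "z")])
}

side_atoms <- function(model, side = c("receptor", "ligand")) {
  side <- match.arg(side)
  chains <- if (side == "receptor") model$receptor_chains else model$ligand_chains
  model$atoms$chain %in% chains
}

#' Read an atomic model from a PDB file
#'
#' Parses coordinates with bio3d and assigns van der Waals radii, atomic
#' numbers and formal side-chain charges from the packaged parameter tables.
#'
#' @param path a PDB coordinate file.
#' @param receptor_chains,ligand_chains chain identifiers for the two sides
#'   of the interface; by default the first chain is the receptor and the
#'   remaining chains the ligand.
#' @return an `atomic_model`.
#' @export
read_structure <- function(path, receptor_chains = NULL, ligand_chains = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("unreadable PDB file ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    resno = a$resno,
    resid = toupper(a$resid),
    atom = a$elety,
    element = element_from_name(a$elety, a$elesy),
    x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE
  )
  chains <- unique(atoms$chain)
  if (is.null(receptor_chains)) receptor_chains <- chains[1]
  if (is.null(ligand_chains)) ligand_chains <- setdiff(chains, receptor_chains)
  atomic_model(atoms, receptor_chains, ligand_chains)
}

#' Write an atomic model to a PDB file
#'
#' @param model an `atomic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resid,
                   chain = a$chain, elety = a$atom, elesy = a$element)
  invisible(path)
}

#' Apply a rigid transform to a model
#'
#' @param model an `atomic_model`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 Angstrom vector.
#' @param pivot rotation center (default: origin).
#' @param sel logical atom selection to transform (default: all atoms).
#' @return the transformed `atomic_model`.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0),
                            pivot = c(0, 0, 0), sel = TRUE) {
  xyz <- atom_coords(model)
  idx <- if (isTRUE(sel)) seq_len(nrow(xyz)) else which(sel)
  moved <- sweep(xyz[idx, , drop = FALSE], 2, pivot) %*% t(rotation)
  moved <- sweep(moved, 2, pivot + translation, `+`)
  model$atoms[idx, c("x", "y", "z")] <- moved
  model
}
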