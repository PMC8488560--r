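# Interface energetics: a generic pairwise energy function (Coulomb with a
# distance-dependent dielectric plus a 12-6 steric term), computational
# alanine scanning (side-chain truncation beyond C-beta at fixed
# coordinates), constellation (residue-group) scanning with cooperativity,
# hot-spot thresholding, and salt-bridge detection.
#
# The energy function is an explicitly generic stand-in: absolute ddG
# magnitudes depend on the forcefield and are not comparable across energy
# models; the scan machinery, thresholds and cooperativity arithmetic are
# the point.

#' Interface energy model
#'
#' Coulomb term `k * qi * qj / (dielectric_factor * r^2)` (i.e. a
#' distance-dependent dielectric `eps(r) = dielectric_factor * r`) plus a
#' 12-6 steric term `lj_well * ((s/r)^12 - 2 (s/r)^6)` with `s = ri + rj`,
#' summed over receptor-ligand atom pairs within `cutoff_A`.  Energies are
#' in kJ/mol throughout.
#'
#' @param coulomb_k Coulomb constant in kJ mol^-1 A e^-2.
#' @param dielectric_factor slope of the distance-dependent dielectric.
#' @param lj_well steric well depth in kJ/mol.
#' @param cutoff_A nonbonded cutoff in Angstrom.
#' @param hard_core_A pair distances below this trigger a clash warning.
#' @return an `energy_model`.
#' @export
energy_model <- function(coulomb_k = 1389.35, dielectric_factor = 4,
                         lj_well = 0.25, cutoff_A = 8, hard_core_A = 1.5) {
  if (cutoff_A <= 0) stop("`cutoff_A` must be > 0")
  structure(list(coulomb_k = coulomb_k, dielectric_factor = dielectric_factor,
                 lj_well = lj_well, cutoff_A = cutoff_A,
                 hard_core_A = hard_core_A),
            class = "energy_model")
}

#' Receptor-ligand interface energy
#'
#' Sums the pairwise energy over all receptor-ligand atom pairs within the
#' cutoff; intramolecular terms are excluded (coordinates are fixed, so they
#' cancel in every ddG).
#'
#' @param model an `atomic_model` with non-empty receptor and ligand sides.
#' @param energy an [energy_model()].
#' @param warn_clashes warn about atom pairs below the hard-core distance.
#' @return interface energy in kJ/mol.
#' @export
interface_energy <- function(model, energy = energy_model(), warn_clashes = TRUE) {
  rsel <- side_atoms(model, "receptor")
  lsel <- side_atoms(model, "ligand")
  if (!any(rsel) || !any(lsel))
    stop("model must have non-empty receptor and ligand partitions")
  rxyz <- atom_coords(model, rsel)
  lxyz <- atom_coords(model, lsel)
  rq <- model$atoms$charge[rsel]; lq <- model$atoms$charge[lsel]
  rr <- model$atoms$radius[rsel]; lr <- model$atoms$radius[lsel]

  d2 <- outer(rowSums(rxyz^2), rowSums(lxyz^2), "+") - 2 * rxyz %*% t(lxyz)
  d <- sqrt(pmax(d2, 0))
  within <- d <= energy$cutoff_A & d > 0
  if (!any(within)) return(0)
  if (warn_clashes) {
    clash <- which(d < energy$hard_core_A & d > 0, arr.ind = TRUE)
    if (nrow(clash))
      warning(sprintf("%d atom pair(s) below the %.2f A hard core, closest %.2f A",
                      nrow(clash), energy$hard_core_A, min(d[d > 0])))
  }
  qq <- outer(rq, lq)
  ss <- outer(rr, lr, "+")
  dc <- d[within]
  e_coul <- energy$coulomb_k * qq[within] / (energy$dielectric_factor * dc^2)
  sr6 <- (ss[within] / dc)^6
  e_lj <- energy$lj_well * (sr6^2 - 2 * sr6)
  sum(e_coul + e_lj)
}

residue_table <- function(model, sel) {
  unique(model$atoms[sel, c("chain", "resno", "resid")])
}

# Drop side-chain atoms beyond C-beta for the listed residues (keys =
# "chain:resno"); backbone and CB keep their coordinates.
truncate_to_alanine <- function(model, keys) {
  a <- model$atoms
  akey <- paste(a$chain, a$resno, sep = ":")
  drop <- akey %in% keys & !(a$atom %in% c(BACKBONE_ATOMS, "CB"))
  model$atoms <- a[!drop, , drop = FALSE]
  rownames(model$atoms) <- NULL
  model
}

residue_keys <- function(chain, resno) paste(chain, resno, sep = ":")

# Parse constellation member labels of the chain-prefixed form "B804" (or
# "chain:resno") into keys.
parse_residue_label <- function(label) {
  if (grepl(":", label)) return(label)
  sub("^(.)(\\d+)$", "\\1:\\2", label)
}

#' Computational alanine scan of one interface side
#'
#' For each residue on the chosen side, `ddG = E(side chain truncated
#' beyond C-beta) - E(wild type)` with all coordinates fixed (single-point
#' scanning, no re-minimization): a residue whose contacts stabilize the
#' interface (negative interaction energy lost on truncation) gets a
#' positive ddG, the convention under which hot spots sit at or above the
#' +5 kJ/mol threshold.  Gly and Ala give 0 by construction;
#' Pro is scanned by the same rule with a warning; non-Gly/Ala residues
#' without a C-beta are skipped with a warning.
#'
#' @param model an `atomic_model`.
#' @param side `"receptor"` or `"ligand"`: which chains to scan.
#' @param energy an [energy_model()].
#' @return a `scan_result` data.frame: `chain`, `resno`, `resid`, `ddG`
#'   (kJ/mol), sorted by chain and residue number.
#' @export
alanine_scan <- function(model, side = c("ligand", "receptor"),
                         energy = energy_model()) {
  side <- match.arg(side)
  sel <- side_atoms(model, side)
  res <- residue_table(model, sel)
  res <- res[order(res$chain, res$resno), ]
  e_wt <- interface_energy(model, energy, warn_clashes = FALSE)

  ddg <- numeric(nrow(res))
  keep <- rep(TRUE, nrow(res))
  a <- model$atoms
  for (i in seq_len(nrow(res))) {
    key <- residue_keys(res$chain[i], res$resno[i])
    if (res$resid[i] %in% c("GLY", "ALA")) { ddg[i] <- 0; next }
    ratoms <- a$atom[paste(a$chain, a$resno, sep = ":") == key]
    if (!"CB" %in% ratoms) {
      warning(sprintf("residue %s %s has no CB; skipped", res$resid[i], key))
      keep[i] <- FALSE
      next
    }
    if (res$resid[i] == "PRO")
      warning(sprintf("proline %s scanned by C-beta truncation", key))
    mut <- truncate_to_alanine(model, key)
    ddg[i] <- interface_energy(mut, energy, warn_clashes = FALSE) - e_wt
  }
  out <- data.frame(chain = res$chain, resno = res$resno, resid = res$resid,
                    ddG = ddg, stringsAsFactors = FALSE)[keep, ]
  rownames(out) <- NULL
  attr(out, "side") <- side
  attr(out, "e_wildtype") <- e_wt
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Cooperativity of a residue constellation
#'
#' The defining arithmetic of constellation analysis: cooperativity is the
#' group's simultaneous-truncation ddG minus the sum of its members'
#' individual ddGs.  Negative cooperativity means the group contributes less
#' than its parts (redundant contacts); positive means synergy.
#'
#' @param constellation_ddg group ddG in kJ/mol.
#' @param summed_individual_ddg sum of the members' individual ddGs, kJ/mol.
#' @return cooperativity in kJ/mol.
#' @export
cooperativity <- function(constellation_ddg, summed_individual_ddg) {
  constellation_ddg - summed_individual_ddg
}

#' Constellation (residue-group) scan
#'
#' For each group, all members are truncated to alanine simultaneously:
#' `constellation ddG = E(all truncated) - E(wild type)`.  The summed
#' individual ddGs come from [alanine_scan()], and cooperativity is their
#' difference via [cooperativity()].
#'
#' @param model an `atomic_model`.
#' @param groups list of character vectors of residue labels, either
#'   chain-prefixed (`"B804"`) or `"chain:resno"`.
#' @param side which side the residues belong to.
#' @param energy an [energy_model()].
#' @param scan optional precomputed [alanine_scan()] result for the side.
#' @return a data.frame with `constellation`, `constellation_ddG`,
#'   `summed_individual_ddG`, `cooperativity` (all kJ/mol).
#' @export
constellation_scan <- function(model, groups, side = c("ligand", "receptor"),
                               energy = energy_model(), scan = NULL) {
  side <- match.arg(side)
  if (is.null(scan)) scan <- alanine_scan(model, side, energy)
  scan_key <- residue_keys(scan$chain, scan$resno)
  e_wt <- attr(scan, "e_wildtype")
  if (is.null(e_wt)) e_wt <- interface_energy(model, energy, warn_clashes = FALSE)

  rows <- lapply(groups, function(g) {
    if (!length(g)) stop("empty constellation group")
    keys <- vapply(g, parse_residue_label, character(1))
    missing <- setdiff(keys, scan_key)
    if (length(missing))
      stop("constellation member(s) not scannable in the model: ",
           paste(missing, collapse = ", "))
    mut <- truncate_to_alanine(model, keys)
    cddg <- interface_energy(mut, energy, warn_clashes = FALSE) - e_wt
    sddg <- sum(scan$ddG[match(keys, scan_key)])
    data.frame(constellation = paste(gsub(":", "", g), collapse = "_"),
               constellation_ddG = cddg,
               summed_individual_ddG = sddg,
               cooperativity = cooperativity(cddg, sddg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("constellation_result", "data.frame")
  out
}

#' Hot-spot and constellation-candidate report
#'
#' Hot spots are residues with ddG at or above `single_threshold`
#' (inclusive, default 5 kJ/mol); constellation candidates have ddG strictly
#' greater than `constellation_threshold` (default 3 kJ/mol).  Both lists
#' are sorted by descending ddG.
#'
#' @param scan a [alanine_scan()] result.
#' @param single_threshold inclusive hot-spot threshold, kJ/mol.
#' @param constellation_threshold strict candidate threshold, kJ/mol.
#' @return a list with `hotspots`, `constellation_candidates` (data.frames)
#'   and the thresholds used.
#' @export
hotspot_report <- function(scan, single_threshold = 5,
                           constellation_threshold = 3) {
  if (single_threshold <= 0 || constellation_threshold <= 0)
    stop("thresholds must be > 0")
  ord <- scan[order(-scan$ddG), , drop = FALSE]
  rownames(ord) <- NULL
  list(hotspots = ord[ord$ddG >= single_threshold, , drop = FALSE],
       constellation_candidates = ord[ord$ddG > constellation_threshold, ,
                                      drop = FALSE],
       single_threshold = single_threshold,
       constellation_threshold = constellation_threshold)
}

BASIC_SIDECHAIN <- data.frame(
  resid = c("LYS", "ARG", "ARG", "ARG"),
  atom = c("NZ", "NE", "NH1", "NH2"), stringsAsFactors = FALSE)
ACIDIC_SIDECHAIN <- data.frame(
  resid = c("ASP", "ASP", "GLU", "GLU"),
  atom = c("OD1", "OD2", "OE1", "OE2"), stringsAsFactors = FALSE)

#' Cross-interface salt bridges
#'
#' All (basic side-chain nitrogen, acidic side-chain oxygen) residue pairs
#' across the receptor-ligand interface whose minimum atom distance is at or
#' below the cutoff.  Basic set: Lys NZ, Arg NE/NH1/NH2; acidic set: Asp
#' OD1/OD2, Glu OE1/OE2.  Symmetric in receptor/ligand labeling.
#'
#' @param model an `atomic_model`.
#' @param distance_cutoff_A maximum N-O distance in Angstrom (default 4.0).
#' @return data.frame with the basic and acidic residues, their sides, and
#'   the minimum atom distance of each pair.
#' @export
salt_bridges <- function(model, distance_cutoff_A = 4.0) {
  a <- model$atoms
  side <- ifelse(a$chain %in% model$receptor_chains, "receptor",
                 ifelse(a$chain %in% model$ligand_chains, "ligand", NA))
  basic <- which(paste(a$resid, a$atom) %in%
                   paste(BASIC_SIDECHAIN$resid, BASIC_SIDECHAIN$atom) & !is.na(side))
  acidic <- which(paste(a$resid, a$atom) %in%
                    paste(ACIDIC_SIDECHAIN$resid, ACIDIC_SIDECHAIN$atom) & !is.na(side))
  empty <- data.frame(basic_chain = character(), basic_resno = integer(),
                      basic_resid = character(), basic_side = character(),
                      acidic_chain = character(), acidic_resno = integer(),
                      acidic_resid = character(), acidic_side = character(),
                      min_distance_A = numeric(), stringsAsFactors = FALSE)
  if (!length(basic) || !length(acidic)) return(empty)

  bxyz <- atom_coords(model, basic)
  axyz <- atom_coords(model, acidic)
  d <- sqrt(pmax(outer(rowSums(bxyz^2), rowSums(axyz^2), "+") -
                   2 * bxyz %*% t(axyz), 0))
  cross <- outer(side[basic], side[acidic], `!=`)
  hits <- which(d <= distance_cutoff_A & cross, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)

  out <- data.frame(
    basic_chain = a$chain[basic[hits[, 1]]],
    basic_resno = a$resno[basic[hits[, 1]]],
    basic_resid = a$resid[basic[hits[, 1]]],
    basic_side = side[basic[hits[, 1]]],
    acidic_chain = a$chain[acidic[hits[, 2]]],
    acidic_resno = a$resno[acidic[hits[, 2]]],
    acidic_resid = a$resid[acidic[hits[, 2]]],
    acidic_side = side[acidic[hits[, 2]]],
    distance_A = d[hits], stringsAsFactors = FALSE)
  # reduce atom pairs to residue pairs at their minimum distance
  key <- paste(out$basic_chain, out$basic_resno, out$acidic_chain, out$acidic_resno)
  keep <- !duplicated(key[order(out$distance_A)])
  out <- out[order(out$distance_A), ][keep, ]
  names(out)[names(out) == "distance_A"] <- "min_distance_A"
  out <- out[order(out$basic_chain, out$basic_resno, out$acidic_chain,
                   out$acidic_resno), ]
  rownames(out) <- NULL
  out
}

#' Write a scan or constellation table as TSV
#' @param x a `scan_result` or `constellation_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
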