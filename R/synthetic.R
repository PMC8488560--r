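# Seeded synthetic-data generators: reconstruction ensembles of a known
# ground truth with i.i.d. Gaussian noise, optional planted "ligand"
# density and B-factor-like radial attenuation, and toy two-chain atomic
# complexes with charged interface residues.  All generators are pure
# functions of their arguments (seed included).

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(expr)
}

gaussian_blob <- function(d, voxel, center_A, sigma_A, peak = 1) {
  ax <- lapply(1:3, function(k) ((0:(d[k] - 1)) * voxel - center_A[k])^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  peak * exp(-r2 / (2 * sigma_A^2))
}

#' Synthetic ground-truth density: a pseudo-atomic cage fragment
#'
#' Pseudo-atoms arranged on three arcs converging near the box centre (a
#' cartoon of three curved legs meeting at a vertex hub), each rendered as a
#' Gaussian blob; the field is normalized to unit peak.  Deterministic:
#' contains no random numbers.
#'
#' @param dim_vox box size in voxels (cubic).
#' @param voxel_size voxel size in Angstrom.
#' @param n_arcs number of arcs.
#' @param atoms_per_arc pseudo-atoms per arc.
#' @param arc_radius_A arc radius in Angstrom.
#' @param blob_sigma_A Gaussian width of each pseudo-atom.
#' @return a [voxel_grid()] with unit maximum.
#' @export
make_ground_truth <- function(dim_vox = 48, voxel_size = 2, n_arcs = 3,
                              atoms_per_arc = 16, arc_radius_A = 26,
                              blob_sigma_A = 5) {
  d <- rep(as.integer(dim_vox), 3)
  box_A <- (d - 1) * voxel_size
  centre <- box_A / 2
  data <- array(0, dim = d)
  for (a in seq_len(n_arcs)) {
    phi <- 2 * pi * (a - 1) / n_arcs
    # arc in a tilted plane, starting near the centre and curving outwards
    tpar <- seq(0.08, 0.62, length.out = atoms_per_arc)
    theta <- tpar * pi
    pts <- cbind(
      centre[1] + arc_radius_A * sin(theta) * cos(phi) - 4 * cos(phi),
      centre[2] + arc_radius_A * sin(theta) * sin(phi) - 4 * sin(phi),
      centre[3] + arc_radius_A * (cos(theta) - cos(theta[1])) * 0.6 +
        3 * sin(2 * phi)
    )
    for (i in seq_len(nrow(pts)))
      data <- data + gaussian_blob(d, voxel_size, pts[i, ], blob_sigma_A)
  }
  data <- data / max(data)
  voxel_grid(data, voxel_size)
}

#' Generate a synthetic reconstruction ensemble
#'
#' Each member is the ground truth (plus planted ligand density, if any)
#' with a fresh i.i.d. real-space Gaussian noise realization, optionally
#' degraded by a B-factor-like radial attenuation — a stand-in for a set of
#' independent sub-map reconstructions of one condition.  Deterministic
#' given the seed.
#'
#' @param n number of member maps (>= 2).
#' @param noise_sigma per-voxel noise standard deviation, in units of the
#'   ground-truth peak (which is 1).  The default 0.02 (peak signal-to-noise
#'   50 per member) reflects the high low-frequency agreement of real
#'   reconstruction sub-maps.
#' @param ground_truth a [voxel_grid()]; default [make_ground_truth()].
#' @param ligand optional list describing a planted spherical ligand blob:
#'   `center_A` (defaults to a site near the first arc), `sigma_A` (default
#'   5, so the blob passes an 11 A low-pass intact) and `peak` amplitude
#'   (default 0.05, five times the standard error of a 4-member condition
#'   mean at the default noise level).
#' @param b_factor radial attenuation in Angstrom^2 applied to every member
#'   (0 = none); see [apply_radial_attenuation()].
#' @param seed RNG seed.
#' @param label condition label.
#' @return a list with `ensemble` ([map_ensemble()]), `ground_truth`, and
#'   `ligand_mask` (binary [voxel_grid()] of voxels where the planted
#'   density exceeds half its maximum, or NULL).
#' @export
make_ensemble <- function(n = 4, noise_sigma = 0.02,
                          ground_truth = make_ground_truth(),
                          ligand = NULL, b_factor = 0, seed = 1,
                          label = "synthetic") {
  if (n < 2) stop("an ensemble needs n >= 2 members")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  d <- dim(ground_truth$data)
  truth <- ground_truth$data
  ligand_mask <- NULL
  if (!is.null(ligand)) {
    center <- ligand$center_A
    if (is.null(center)) center <- (d - 1) * ground_truth$voxel_size / 2 +
        c(18, 10, 6)
    sigma_A <- if (is.null(ligand$sigma_A)) 5 else ligand$sigma_A
    peak <- if (is.null(ligand$peak)) 0.05 else ligand$peak
    lig <- gaussian_blob(d, ground_truth$voxel_size, center, sigma_A, peak)
    truth <- truth + lig
    ligand_mask <- grid_with_data(ground_truth,
                                  array(as.numeric(lig > max(lig) / 2), dim = d))
  }
  members <- with_seed(seed, lapply(seq_len(n), function(i) {
    g <- grid_with_data(ground_truth,
                        truth + array(stats::rnorm(prod(d), sd = noise_sigma),
                                      dim = d))
    if (b_factor > 0) g <- apply_radial_attenuation(g, b_factor) else g
  }))
  list(ensemble = map_ensemble(members, label = label),
       ground_truth = grid_with_data(ground_truth, truth),
       ligand_mask = ligand_mask)
}

TOY_BACKBONE <- list(  # offsets from CA, Angstrom
  N  = c(-1.20, -0.45, 0.00),
  CA = c(0.00, 0.00, 0.00),
  C  = c(1.25, -0.45, 0.00),
  O  = c(1.35, -1.65, 0.15)
)

#' Generate a toy two-chain complex with a charged interface
#'
#' Two extended pseudo-protein strands facing each other across an
#' interface: chain R (receptor) and chain L (ligand), residues spaced
#' 3.6 Angstrom along x, backbone N/CA/C/O plus C-beta for every non-Gly
#' residue, and charged termini (Lys NZ or Glu OE1/OE2 pseudo-atoms)
#' pointing into the interface for a seeded random subset of residues.
#' Charged residues on opposite chains are staggered so that some form
#' salt-bridge-range contacts.  Deterministic given the seed.
#'
#' @param n_res_receptor,n_res_ligand residues per chain.
#' @param charged_fraction fraction of residues given a charged side chain.
#' @param separation_A closest-approach gap between the chains' side-chain
#'   termini, Angstrom.
#' @param clash_limit_A minimum allowed interatomic distance; impossible
#'   geometry is rejected.
#' @param seed RNG seed.
#' @return an `atomic_model` with an attribute `"contacts"`: the residue
#'   pairs across the interface with any atoms within 6 Angstrom.
#' @export
make_toy_complex <- function(n_res_receptor = 12, n_res_ligand = 10,
                             charged_fraction = 0.4, separation_A = 3.5,
                             clash_limit_A = 2.0, seed = 1) {
  if (separation_A < clash_limit_A)
    stop(sprintf("separation %.2f A below the clash limit %.2f A",
                 separation_A, clash_limit_A))
  # side chains extend 1.5 (CB) + 1.5 (terminus) A towards the interface
  reach <- 3.0
  gap_y <- separation_A + 2 * reach

  build_chain <- function(chain, n_res, y0, dir, charged, kinds, x0) {
    rows <- list()
    for (i in seq_len(n_res)) {
      ca <- c(x0 + (i - 1) * 3.6, y0, 0.4 * ((i %% 2) * 2 - 1))
      resid <- if (charged[i]) kinds[i] else "SER"
      for (at in names(TOY_BACKBONE))
        rows[[length(rows) + 1]] <- data.frame(
          chain = chain, resno = i, resid = resid, atom = at,
          element = substr(at, 1, 1),
          x = ca[1] + TOY_BACKBONE[[at]][1],
          y = ca[2] + TOY_BACKBONE[[at]][2],
          z = ca[3] + TOY_BACKBONE[[at]][3], stringsAsFactors = FALSE)
      cb <- ca + c(0, dir * 1.5, 0)
      rows[[length(rows) + 1]] <- data.frame(
        chain = chain, resno = i, resid = resid, atom = "CB", element = "C",
        x = cb[1], y = cb[2], z = cb[3], stringsAsFactors = FALSE)
      if (charged[i]) {
        tip <- ca + c(0, dir * reach, 0)
        if (kinds[i] == "LYS") {
          rows[[length(rows) + 1]] <- data.frame(
            chain = chain, resno = i, resid = resid, atom = "NZ",
            element = "N", x = tip[1], y = tip[2], z = tip[3],
            stringsAsFactors = FALSE)
        } else {
          for (k in 1:2)
            rows[[length(rows) + 1]] <- data.frame(
              chain = chain, resno = i, resid = resid,
              atom = paste0("OE", k), element = "O",
              x = tip[1] + (k - 1.5) * 1.2, y = tip[2], z = tip[3],
              stringsAsFactors = FALSE)
        }
      } else {
        og <- ca + c(0, dir * 2.4, 0)
        rows[[length(rows) + 1]] <- data.frame(
          chain = chain, resno = i, resid = resid, atom = "OG",
          element = "O", x = og[1], y = og[2], z = og[3],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }

  model <- with_seed(seed, {
    pick <- function(n) {
      ch <- rep(FALSE, n)
      ch[sample.int(n, max(1L, round(charged_fraction * n)))] <- TRUE
      ch
    }
    ch_r <- pick(n_res_receptor)
    ch_l <- pick(n_res_ligand)
    # opposite-sign partners: receptor alternates LYS/GLU, ligand the reverse
    kinds_r <- ifelse(seq_len(n_res_receptor) %% 2 == 0, "LYS", "GLU")
    kinds_l <- ifelse(seq_len(n_res_ligand) %% 2 == 0, "GLU", "LYS")
    atoms <- rbind(
      build_chain("R", n_res_receptor, 0, +1, ch_r, kinds_r, x0 = 0),
      build_chain("L", n_res_ligand, gap_y, -1, ch_l, kinds_l, x0 = 1.8)
    )
    atomic_model(atoms, receptor_chains = "R", ligand_chains = "L")
  })

  xyz <- atom_coords(model)
  dmat <- as.matrix(stats::dist(xyz))
  diag(dmat) <- Inf
  # only enforce the clash limit between non-bonded partners (different or
  # non-adjacent residues)
  bonded <- outer(model$atoms$chain, model$atoms$chain, `==`) &
    abs(outer(model$atoms$resno, model$atoms$resno, `-`)) <= 1
  min_sep <- min(dmat[!bonded])
  if (min_sep < clash_limit_A)
    stop(sprintf("generated geometry clashes: min interatomic distance %.2f A",
                 min_sep))

  rsel <- which(side_atoms(model, "receptor"))
  lsel <- which(side_atoms(model, "ligand"))
  cross <- dmat[rsel, lsel, drop = FALSE]
  hits <- which(cross <= 6, arr.ind = TRUE)
  contacts <- unique(data.frame(
    receptor_resno = model$atoms$resno[rsel[hits[, 1]]],
    ligand_resno = model$atoms$resno[lsel[hits[, 2]]]))
  contacts <- contacts[order(contacts$receptor_resno, contacts$ligand_resno), ]
  rownames(contacts) <- NULL
  attr(model, "contacts") <- contacts
  attr(model, "min_separation_A") <- min_sep
  model
}
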