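# Shared fixtures and independent brute-force oracles.  The oracles
# deliberately use naive explicit loops (or base-R statistical functions)
# rather than any package code path.

random_grid <- function(d = 8, voxel = 2, seed = 1, origin = c(0, 0, 0)) {
  set.seed(seed)
  voxel_grid(array(rnorm(d^3), dim = rep(d, 3)), voxel, origin)
}

# Integer-rounded Fourier shell of voxel (i,j,k) (0-based), cubic grid,
# computed with explicit wrapping.
oracle_shell <- function(i, j, k, n) {
  w <- function(f) if (f > n / 2) f - n else f
  as.integer(round(sqrt(w(i)^2 + w(j)^2 + w(k)^2)))
}

# Naive radial amplitude profile: loop every Fourier voxel, group by shell.
oracle_profile <- function(data) {
  n <- dim(data)[1]
  ft <- fft(data)
  nyq <- floor(n / 2)
  sums <- numeric(nyq + 1)
  counts <- integer(nyq + 1)
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) for (k in 0:(n - 1)) {
    s <- oracle_shell(i, j, k, n)
    if (s <= nyq) {
      sums[s + 1] <- sums[s + 1] + Mod(ft[i + 1, j + 1, k + 1])
      counts[s + 1] <- counts[s + 1] + 1L
    }
  }
  list(mean_amplitude = sums / counts, shell_count = counts)
}

# Naive low-pass: build the shell-indexed raised-cosine multiplier voxel by
# voxel (the filter is constant within each integer-rounded shell).
oracle_lowpass <- function(data, voxel, cutoff_A, ew = 3) {
  n <- dim(data)[1]
  ft <- fft(data)
  r_c <- n * voxel / cutoff_A
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) for (k in 0:(n - 1)) {
    r <- oracle_shell(i, j, k, n)
    h <- if (r <= r_c) 1 else if (r >= r_c + ew) 0 else
      0.5 * (1 + cos(pi * (r - r_c) / ew))
    ft[i + 1, j + 1, k + 1] <- ft[i + 1, j + 1, k + 1] * h
  }
  Re(fft(ft, inverse = TRUE)) / length(ft)
}

# Naive threshold + Euclidean dilation: a voxel is in the dilated mask if
# any voxel within the radius is above threshold.
oracle_binary_mask <- function(data, thr, extend) {
  d <- dim(data)
  out <- array(FALSE, dim = d)
  above <- which(data >= thr, arr.ind = TRUE)
  if (nrow(above) == 0) return(out)
  idx <- which(array(TRUE, dim = d), arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    dd <- sweep(above, 2, idx[v, ])
    if (any(rowSums(dd^2) <= extend^2)) out[idx[v, 1], idx[v, 2], idx[v, 3]] <- TRUE
  }
  out
}

# Naive masked Pearson correlation from sum formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# Naive pairwise interface energy by explicit double loop.
oracle_energy <- function(model, em) {
  a <- model$atoms
  rsel <- which(a$chain %in% model$receptor_chains)
  lsel <- which(a$chain %in% model$ligand_chains)
  e <- 0
  for (i in rsel) for (j in lsel) {
    r <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
    if (r > 0 && r <= em$cutoff_A) {
      e <- e + em$coulomb_k * a$charge[i] * a$charge[j] /
        (em$dielectric_factor * r^2)
      sr6 <- ((a$radius[i] + a$radius[j]) / r)^6
      e <- e + em$lj_well * (sr6^2 - 2 * sr6)
    }
  }
  e
}

# A compact helix-like single-chain ligand model (~60 atoms) used by the
# fit-scoring tests.
toy_ligand <- function(n_res = 15) {
  t <- seq(0, 4 * pi, length.out = n_res)
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    ca <- c(5 * cos(t[i]), 5 * sin(t[i]), 1.5 * i)
    data.frame(chain = "L", resno = i, resid = "ALA",
               atom = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"),
               x = ca[1] + c(-1.2, 0, 1.25, 1.35),
               y = ca[2] + c(-0.45, 0, -0.45, -1.65),
               z = ca[3] + c(0, 0, 0, 0.15),
               stringsAsFactors = FALSE)
  }))
  atomic_model(atoms, receptor_chains = character(0), ligand_chains = "L")
}

# Ensemble of constant-valued maps (every voxel of member i equals vals[i]).
const_ensemble <- function(vals, d = 2, voxel = 1) {
  map_ensemble(lapply(vals, function(v)
    voxel_grid(array(v, dim = rep(d, 3)), voxel)))
}

# Two-residue charged fixture: one Lys NZ on the receptor facing one Glu
# on the ligand, mirrored across the interface so the NZ-OE1 distance is
# exactly `no_dist`.
charged_pair <- function(no_dist = 3.5) {
  y0 <- 3.0 + no_dist   # ligand tip plane
  atoms <- data.frame(
    chain = c(rep("R", 6), rep("L", 7)),
    resno = 1L,
    resid = c(rep("LYS", 6), rep("GLU", 7)),
    atom = c("N", "CA", "C", "O", "CB", "NZ",
             "N", "CA", "C", "O", "CB", "OE1", "OE2"),
    element = c("N", "C", "C", "O", "C", "N",
                "N", "C", "C", "O", "C", "O", "O"),
    x = c(-1.2, 0, 1.25, 1.35, 0, 0,
          -1.2, 0, 1.25, 1.35, 0, 0, 1.2),
    y = c(-0.45, 0, -0.45, -1.65, 1.5, 3.0,
          y0 + 3.45, y0 + 3.0, y0 + 3.45, y0 + 4.65, y0 + 1.5, y0, y0),
    z = 0, stringsAsFactors = FALSE)
  atomic_model(atoms, "R", "L")
}
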