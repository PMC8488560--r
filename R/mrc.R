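# MRC2014 volume I/O.
#
# Volumes are written as 32-bit float (mode 2), axis order MAPC/MAPR/MAPS =
# 1,2,3, little-endian; the voxel size is carried in the cell dimensions
# (CELLA) divided by the sampling counts (MX/MY/MZ).  Only isotropic volumes
# are accepted: anisotropy beyond a 1e-3 relative tolerance is rejected
# rather than silently resampled, since resampling would corrupt the
# voxel-wise statistics downstream.

MRC_HEADER_BYTES <- 1024L

#' Read an MRC2014 density volume
#'
#' @param path path to an MRC file.
#' @return a [voxel_grid()].  The voxel size is `CELLA / (MX,MY,MZ)`; the
#'   origin is taken from the MRC2014 ORIGIN record.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", MRC_HEADER_BYTES)
  if (length(hdr) < MRC_HEADER_BYTES)
    stop("malformed MRC header: file shorter than 1024 bytes")
  ints <- readBin(hdr, "integer", 256L, size = 4L, endian = "little")
  flts <- readBin(hdr, "double", 256L, size = 4L, endian = "little")

  nxyz <- ints[1:3]
  mode <- ints[4]
  mxyz <- ints[8:10]
  cella <- flts[11:13]
  mapcrs <- ints[17:19]
  nsymbt <- ints[24]
  origin <- flts[50:52]
  map_id <- rawToChar(hdr[(52L * 4L + 1L):(52L * 4L + 4L)])

  if (any(nxyz < 1L) || any(nxyz > 4096L))
    stop("malformed MRC header: NX/NY/NZ = ", paste(nxyz, collapse = ","))
  if (mode != 2L)
    stop("unsupported MRC MODE ", mode,
         ": only mode 2 (32-bit float) volumes are handled")
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported axis order MAPC/MAPR/MAPS = ",
         paste(mapcrs, collapse = ","), " (expected 1,2,3)")
  if (any(mxyz < 1L))
    stop("malformed MRC header: MX/MY/MZ = ", paste(mxyz, collapse = ","))

  vox <- cella / mxyz
  if (any(!is.finite(vox)) || any(vox <= 0))
    stop("malformed MRC header: CELLA = ", paste(signif(cella, 5), collapse = ","))
  if ((max(vox) - min(vox)) > 1e-3 * mean(vox))
    stop(sprintf(
      "anisotropic voxel size in CELLA/MX..MZ: (%.5g, %.5g, %.5g) A; only isotropic volumes are supported",
      vox[1], vox[2], vox[3]))
  if (!identical(map_id, "MAP "))
    warning("MRC 'MAP ' signature missing; attempting to read anyway")

  if (nsymbt > 0L) readBin(con, "raw", nsymbt)
  n <- prod(nxyz)
  vals <- readBin(con, "double", n, size = 4L, endian = "little")
  if (length(vals) < n)
    stop("malformed MRC file: expected ", n, " voxels, got ", length(vals))
  voxel_grid(array(vals, dim = nxyz), voxel_size = mean(vox), origin = origin)
}

#' Write an MRC2014 density volume
#'
#' Writes mode-2 (32-bit float) little-endian volumes.  Round-tripping with
#' [read_map()] preserves values at float32 precision, and exactly for data
#' already representable in float32.
#'
#' @param grid a [voxel_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(grid, path) {
  if (!is.voxel_grid(grid)) stop("`grid` must be a voxel_grid")
  if (anyNA(grid$data)) {
    warning("NA voxels written as 0 (MRC has no missing-value code)")
    grid <- grid_with_data(grid, ifelse(is.na(grid$data), 0, grid$data))
  }
  d <- dim(grid$data)
  v <- grid$voxel_size
  st <- grid_stats(grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                      # 1-3   NX NY NZ
  wi(2L)                     # 4     MODE 2 = float32
  wi(c(0L, 0L, 0L))          # 5-7   NXSTART..
  wi(d)                      # 8-10  MX MY MZ
  wf(d * v)                  # 11-13 CELLA
  wf(c(90, 90, 90))          # 14-16 CELLB
  wi(c(1L, 2L, 3L))          # 17-19 MAPC MAPR MAPS
  wf(c(min(grid$data), max(grid$data), st$mean))  # 20-22 DMIN DMAX DMEAN
  wi(1L)                     # 23    ISPG (volume)
  wi(0L)                     # 24    NSYMBT
  wi(integer(25L))           # 25-49 EXTRA
  wf(grid$origin)            # 50-52 ORIGIN
  writeBin(charToRaw("MAP "), con)                 # 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # 54 MACHST little-endian
  wf(st$sigma)               # 55    RMS
  wi(0L)                     # 56    NLABL
  writeBin(raw(800L), con)   # 57-256 labels
  writeBin(as.numeric(grid$data), con, size = 4L, endian = "little")
  invisible(path)
}
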