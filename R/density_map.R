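#' @title Electron-density maps
#' @description
#' A \code{DensityMap} holds a 3-D grid in CCP4/MRC storage order
#' (dimension 1 = fastest/column axis), the unit-cell geometry, the axis
#' permutation (\code{axis_order[k]} is the crystal axis stored along grid
#' dimension k), the start voxel offsets and the per-cell sampling
#' intervals. World coordinates are related to grid indices through the
#' standard crystallographic orthogonalization matrix, so maps with
#' permuted axis encodings of the same field interpolate identically. An
#' axis is treated as crystal-periodic when the stored sample count equals
#' the cell interval count along that axis.
#' @name DensityMap
NULL

orth_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(
    a, b * cos(ga), cc * cos(be),
    0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0, 0, cc * v / sin(ga)
  ), 3, 3, byrow = TRUE)
}

new_density_map <- function(grid, cell, axis_order, start, intervals,
                            normalized = FALSE,
                            raw_mean = NA_real_, raw_sd = NA_real_) {
  if (length(dim(grid)) != 3 || any(dim(grid) < 2))
    stop("grid must be a 3-D array with >= 2 samples per axis")
  M <- orth_matrix(cell)
  structure(list(grid = grid, cell = cell, axis_order = as.integer(axis_order),
                 start = as.integer(start), intervals = as.integer(intervals),
                 normalized = normalized, raw_mean = raw_mean, raw_sd = raw_sd,
                 orth = M, deorth = solve(M)),
            class = "DensityMap")
}

#' @export
print.DensityMap <- function(x, ...) {
  cat(sprintf("DensityMap %s  cell %s  axes (%s)  %s\n",
              paste(dim(x$grid), collapse = "x"),
              paste(format(x$cell, digits = 4), collapse = " "),
              paste(x$axis_order, collapse = ","),
              if (x$normalized) "sigma-normalized" else "raw"))
  invisible(x)
}

#' Read a CCP4/MRC electron-density map
#'
#' Supports mode-2 (float32) maps; axis order and start offsets from the
#' header are resolved into a single world-coordinate convention, so two
#' encodings of the same field give the same \code{\link{point_density}}.
#' Raw values are kept; call \code{\link{normalize_map}} before
#' interpolating reliabilities.
#'
#' @param path path to the binary map file.
#' @return A \code{DensityMap}.
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) stop("corrupt map header: file shorter than 1024 bytes")
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nc <- ints[1]; nr <- ints[2]; ns <- ints[3]; mode <- ints[4]
  start <- ints[5:7]; intervals <- ints[8:10]
  cell <- readBin(con, "numeric", n = 6, size = 4, endian = "little")
  axes <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # min/max/mean
  readBin(con, "integer", n = 2, size = 4, endian = "little")  # ispg, nsymbt
  seek(con, 52 * 4)
  stamp <- rawToChar(readBin(con, "raw", n = 4))
  if (!identical(substr(stamp, 1, 3), "MAP"))
    stop("corrupt map header: missing MAP stamp")
  if (mode != 2L)
    stop("unsupported map MODE ", mode, " (only mode 2 float32 supported)")
  if (any(c(nc, nr, ns) <= 0) || any(cell[1:3] <= 0))
    stop("corrupt map header: non-positive dimensions or cell")
  if (!setequal(axes, 1:3))
    stop("corrupt map header: MAPC/MAPR/MAPS not a permutation of 1:3")
  seek(con, 1024)
  nvox <- as.numeric(nc) * nr * ns
  if (sz < 1024 + 4 * nvox) stop("truncated map file")
  vals <- readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  grid <- array(vals, dim = c(nc, nr, ns))
  # header start offsets are along the storage axes; convert to the
  # crystal-axis order used internally
  start_crystal <- integer(3)
  start_crystal[axes] <- start
  new_density_map(grid, cell, axes, start_crystal, intervals)
}

#' Write a DensityMap as a CCP4/MRC (mode 2) file
#'
#' @param map a \code{DensityMap}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_map <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  g <- map$grid
  dims <- dim(g)
  writeBin(as.integer(c(dims, 2L, map$start[map$axis_order], map$intervals)),
           con, size = 4, endian = "little")
  writeBin(as.numeric(map$cell), con, size = 4, endian = "little")
  writeBin(as.integer(map$axis_order), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(g), max(g), mean(g))), con, size = 4,
           endian = "little")
  writeBin(c(1L, 0L), con, size = 4, endian = "little")  # ISPG, NSYMBT
  writeBin(integer(52 - 24), con, size = 4, endian = "little")
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  writeBin(as.numeric(stats::sd(as.numeric(g))), con, size = 4,
           endian = "little")
  writeBin(integer(256 - 55), con, size = 4, endian = "little")
  writeBin(as.numeric(g), con, size = 4, endian = "little")
  invisible(path)
}

#' Sigma-normalize a density map
#'
#' Every voxel becomes \code{(value - mean) / sd} over all voxels
#' (population standard deviation). Idempotent up to floating-point
#' round-off; a constant map is a degenerate-map error.
#'
#' @param map a \code{DensityMap}.
#' @return The normalized \code{DensityMap} (mean ~0, sd ~1).
#' @export
normalize_map <- function(map) {
  v <- as.numeric(map$grid)
  mu <- mean(v)
  sig <- sqrt(mean((v - mu)^2))
  if (sig < 1e-12 * max(1, abs(mu))) stop("degenerate map: constant density")
  g <- array((v - mu) / sig, dim = dim(map$grid))
  out <- map
  out$grid <- g
  out$normalized <- TRUE
  out$raw_mean <- if (map$normalized) map$raw_mean else mu
  out$raw_sd <- if (map$normalized) map$raw_sd else sig
  out
}

# continuous 0-based grid coordinate (storage order) of a world point,
# plus per-storage-axis periodicity
grid_coords <- function(map, xyz) {
  frac <- as.numeric(map$deorth %*% xyz)
  t_crystal <- frac * map$intervals - map$start  # crystal-axis order
  u <- t_crystal[map$axis_order]
  periodic <- (dim(map$grid) == map$intervals[map$axis_order])
  list(u = u, periodic = periodic)
}

#' Interpolated point density at a world coordinate
#'
#' Trilinear interpolation in fractional-coordinate space; exact at grid
#' nodes. Crystal periodicity is applied along axes whose stored samples
#' span exactly one full cell; otherwise points outside the sampled extent
#' raise an out-of-bounds error.
#'
#' @param map a \code{DensityMap} (normalize first for sigma units).
#' @param xyz numeric 3-vector (A).
#' @return The interpolated value (sigma units for a normalized map).
#' @export
point_density <- function(map, xyz) {
  gc <- grid_coords(map, xyz)
  u <- gc$u
  dims <- dim(map$grid)
  i0 <- floor(u)
  fr <- u - i0
  idx <- matrix(0L, 2, 3)
  for (k in 1:3) {
    lo <- i0[k]; hi <- i0[k] + 1
    if (gc$periodic[k]) {
      lo <- lo %% dims[k]; hi <- hi %% dims[k]
    } else {
      if (u[k] < -1e-9 || u[k] > dims[k] - 1 + 1e-9)
        stop("point outside non-periodic map extent")
      lo <- max(min(lo, dims[k] - 1), 0)
      hi <- max(min(hi, dims[k] - 1), 0)
    }
    idx[, k] <- c(lo, hi)
  }
  val <- 0
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    w <- (if (a == 1) 1 - fr[1] else fr[1]) *
         (if (b == 1) 1 - fr[2] else fr[2]) *
         (if (cc == 1) 1 - fr[3] else fr[3])
    if (w > 0)
      val <- val + w * map$grid[idx[a, 1] + 1, idx[b, 2] + 1, idx[cc, 3] + 1]
  }
  val
}

#' Is an atom density-reliable?
#'
#' Reliable iff the interpolated density at the atom center is strictly
#' greater than \code{config$density_sigma_cutoff} (1 sigma by default);
#' exactly 1.0 sigma is unreliable.
#'
#' @param map a normalized \code{DensityMap}.
#' @param atom one-row atom data.frame (or list with \code{x,y,z}).
#' @param config a \code{\link{scvar_config}}.
#' @return Logical.
#' @export
atom_reliable <- function(map, atom, config = scvar_config()) {
  if (!isTRUE(map$normalized)) stop("map must be sigma-normalized")
  point_density(map, c(atom$x[1], atom$y[1], atom$z[1])) >
    config$density_sigma_cutoff
}

#' Density reliability of one residue
#'
#' Evaluated on heavy atoms of the first conformer only (config switch for
#' any-conformer evaluation). A residue is reliable when every heavy atom
#' is reliable; its side-chain conformation is reliable when every heavy
#' side-chain atom is. Atoms falling outside a non-periodic map are counted
#' unreliable with a warning rather than aborting the run.
#'
#' @param map a normalized \code{DensityMap}.
#' @param residue a residue from a \code{StructureModel}.
#' @param config a \code{\link{scvar_config}}.
#' @return List of class \code{ReliabilityRecord}: \code{atom_names},
#'   \code{densities} (sigma), \code{atom_reliable},
#'   \code{residue_reliable_all}, \code{residue_reliable_sidechain},
#'   \code{min_sigma}.
#' @export
residue_reliability <- function(map, residue, config = scvar_config()) {
  if (!isTRUE(map$normalized)) stop("map must be sigma-normalized")
  at <- if (isTRUE(config$reliability_first_conformer_only)) {
    first_conformer(residue)$atoms
  } else {
    residue$atoms
  }
  at <- heavy_atoms(at)
  dens <- vapply(seq_len(nrow(at)), function(i) {
    tryCatch(point_density(map, c(at$x[i], at$y[i], at$z[i])),
             error = function(e) {
               warning("atom outside map extent counted unreliable",
                       call. = FALSE)
               -Inf
             })
  }, numeric(1))
  rel <- dens > config$density_sigma_cutoff
  sc <- at$is_sidechain
  structure(list(
    atom_names = at$name,
    densities = dens,
    atom_reliable = rel,
    residue_reliable_all = all(rel),
    residue_reliable_sidechain = if (any(sc)) all(rel[sc]) else TRUE,
    min_sigma = if (length(dens)) min(dens) else NA_real_
  ), class = "ReliabilityRecord")
}

#' Per-residue reliability table for a model
#'
#' @param map a normalized \code{DensityMap}.
#' @param model a \code{StructureModel}.
#' @param config a \code{\link{scvar_config}}.
#' @return data.frame: pdb_id, chain, resnum, resname, n_atoms, min_sigma,
#'   reliable_all, reliable_sidechain — the reliability CSV contract.
#' @export
reliability_table <- function(map, model, config = scvar_config()) {
  rows <- list()
  for (cid in names(model$chains)) {
    for (res in protein_residues(model$chains[[cid]])) {
      rec <- residue_reliability(map, res, config)
      rows[[length(rows) + 1L]] <- data.frame(
        pdb_id = model$pdb_id, chain = cid, resnum = res$number,
        resname = res$res_name, n_atoms = length(rec$densities),
        min_sigma = rec$min_sigma,
        reliable_all = rec$residue_reliable_all,
        reliable_sidechain = rec$residue_reliable_sidechain,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
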