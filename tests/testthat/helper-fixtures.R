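# shared fixture builders and independent oracles

# a random proper rotation + translation
random_rigid <- function(seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 5))
}

apply_rigid <- function(p, rt) as.numeric(rt$R %*% p + rt$t)

# minimal hand-rolled PDB line (fixed columns)
pdb_line <- function(serial, name, res, chain, num, x, y, z,
                     altloc = " ", occ = 1, b = 20, element = NULL,
                     record = "ATOM  ") {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  nm_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm_f, altloc, res, chain, num, x, y, z, occ, b,
          element)
}

# independent trilinear oracle: explicit 8-corner weighted sum using the
# fixture's known orthorhombic geometry (spacing + start offsets)
trilinear_oracle <- function(map, xyz, spacing) {
  stopifnot(identical(map$axis_order, c(1L, 2L, 3L)))
  u <- xyz / spacing - map$start   # orthorhombic, axis_order (1,2,3)
  i0 <- floor(u); fr <- u - i0
  v <- 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    w <- (if (a == 0) 1 - fr[1] else fr[1]) *
         (if (b == 0) 1 - fr[2] else fr[2]) *
         (if (cc == 0) 1 - fr[3] else fr[3])
    v <- v + w * map$grid[i0[1] + a + 1, i0[2] + b + 1, i0[3] + cc + 1]
  }
  v
}

# fabricate a sigma-normalized map directly from a value grid on an
# orthorhombic lattice with given spacing (nodes at integer multiples)
fabricated_map <- function(grid, spacing = 1, normalized = TRUE) {
  dims <- dim(grid)
  m <- scvar:::new_density_map(
    grid, cell = c((dims - 1) * spacing, 90, 90, 90),
    axis_order = c(1, 2, 3), start = c(0, 0, 0), intervals = dims - 1)
  m$normalized <- normalized
  m
}

# one-row atom data.frame at a coordinate
atom_at <- function(x, y, z, name = "CB", element = "C") {
  scvar:::new_atom_table(name, element, x, y, z, "", 1, 20, FALSE)
}

# a single-residue model from an atom table
residue_model <- function(atoms, res_name = "ALA", number = 1,
                          chain = "A", resolution = 1.5) {
  res <- scvar:::new_residue(res_name, number, "", chain, atoms)
  scvar:::new_structure_model("test", resolution,
                              stats::setNames(list(list(res)), chain))
}

# translate every atom of a model by a fixed vector
translate_model <- function(model, d) {
  for (cid in names(model$chains)) {
    for (i in seq_along(model$chains[[cid]])) {
      a <- model$chains[[cid]][[i]]$atoms
      a$x <- a$x + d[1]; a$y <- a$y + d[2]; a$z <- a$z + d[3]
      model$chains[[cid]][[i]]$atoms <- a
    }
  }
  model
}

# brute-force rotation oracle for Kabsch: coarse Euler grid then
# Nelder-Mead refinement of post-rotation rmsd (translation optimal at
# centroid match for any rotation)
rmsd_rotation_oracle <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  }
  f <- function(ang) sqrt(mean(rowSums((t(rot(ang) %*% t(Pc)) - Qc)^2)))
  best <- c(0, 0, 0); best_v <- f(best)
  grid <- seq(-pi, pi, by = pi / 15)
  for (a1 in grid) for (a2 in grid[grid >= -pi / 2 & grid <= pi / 2])
    for (a3 in grid) {
      v <- f(c(a1, a2, a3))
      if (v < best_v) { best_v <- v; best <- c(a1, a2, a3) }
    }
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# default config shared across tests
cfg <- scvar_config()
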