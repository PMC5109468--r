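#' @title Synthetic structure and map generators
#' @description Fixtures with known ground truth: ideal-geometry side chains
#' built by natural-extension (internal -> Cartesian) placement on a helical
#' backbone, variant chain pairs with a known fraction of chi1-changed
#' residues, altloc injection with stated occupancies, and Gaussian-atom
#' density rendering. All generators are deterministic given their seed and
#' leave the caller's RNG state untouched.
#' @name synthetic_fixtures
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# natural extension reference frame: place atom d with given internal
# coordinates relative to ancestors a-b-c so that dihedral(a,b,c,d) = torsion
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ph <- torsion_deg * pi / 180
  d2 <- c(-bond * cos(th), bond * cos(ph) * sin(th), bond * sin(ph) * sin(th))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m2 <- cross3(n, bc)
  M <- cbind(bc, m2, n)
  as.numeric(M %*% d2 + c)
}

element_of <- function(name) {
  nm <- gsub("[0-9']", "", name)
  if (startsWith(nm, "H")) "H" else substr(nm, 1, 1)
}

# side-chain internal-coordinate templates; each atom row:
# name, parents (3 atom names), bond (A), angle (deg), torsion spec.
# torsion spec "chiK" uses chis[K]; "chiK+X" adds a fixed offset; a number
# is a fixed torsion.
SIDECHAIN_TEMPLATES <- list(
  SER = list(
    list("OG", c("N", "CA", "CB"), 1.417, 110.8, "chi1")),
  ASP = list(
    list("CG",  c("N", "CA", "CB"), 1.516, 113.1, "chi1"),
    list("OD1", c("CA", "CB", "CG"), 1.249, 118.5, "chi2"),
    list("OD2", c("CA", "CB", "CG"), 1.249, 118.5, "chi2+180")),
  LEU = list(
    list("CG",  c("N", "CA", "CB"), 1.530, 116.3, "chi1"),
    list("CD1", c("CA", "CB", "CG"), 1.524, 110.7, "chi2"),
    list("CD2", c("CA", "CB", "CG"), 1.525, 110.4, "chi2+122.6")),
  PHE = list(
    list("CG",  c("N", "CA", "CB"), 1.502, 113.8, "chi1"),
    list("CD1", c("CA", "CB", "CG"), 1.390, 120.0, "chi2"),
    list("CD2", c("CA", "CB", "CG"), 1.390, 120.0, "chi2+180"),
    list("CE1", c("CB", "CG", "CD1"), 1.390, 120.0, 180),
    list("CE2", c("CB", "CG", "CD2"), 1.390, 120.0, 180),
    list("CZ",  c("CG", "CD1", "CE1"), 1.390, 120.0, 0)),
  LYS = list(
    list("CG", c("N", "CA", "CB"), 1.520, 114.1, "chi1"),
    list("CD", c("CA", "CB", "CG"), 1.520, 111.3, "chi2"),
    list("CE", c("CB", "CG", "CD"), 1.520, 111.3, "chi3"),
    list("NZ", c("CG", "CD", "CE"), 1.489, 111.9, "chi4")),
  ARG = list(
    list("CG",  c("N", "CA", "CB"), 1.520, 113.8, "chi1"),
    list("CD",  c("CA", "CB", "CG"), 1.520, 111.3, "chi2"),
    list("NE",  c("CB", "CG", "CD"), 1.460, 112.0, "chi3"),
    list("CZ",  c("CG", "CD", "NE"), 1.330, 124.2, "chi4"),
    list("NH1", c("CD", "NE", "CZ"), 1.330, 120.0, 0),
    list("NH2", c("CD", "NE", "CZ"), 1.330, 120.0, 180)),
  MET = list(
    list("CG", c("N", "CA", "CB"), 1.520, 113.3, "chi1"),
    list("SD", c("CA", "CB", "CG"), 1.803, 112.7, "chi2"),
    list("CE", c("CB", "CG", "SD"), 1.791, 100.9, "chi3"))
)

#' Residue types with a build template
#' @return Character vector of 3-letter codes.
#' @export
templated_residues <- function() names(SIDECHAIN_TEMPLATES)

#' Build an ideal-geometry side chain at given chi angles
#'
#' Atoms beyond CB are placed by natural-extension construction from the
#' backbone frame so that \code{\link{measure_chis}} recovers the requested
#' chi values (round trip within 1e-3 degrees). Templated types: Ser, Asp,
#' Leu, Phe, Lys, Arg, Met.
#'
#' @param res_type 3-letter code (must be templated).
#' @param chis requested chi values (degrees); length at most the
#'   template's chi count, remaining slots default to 180.
#' @param backbone_frame list with 3-vectors \code{N}, \code{CA}, \code{C}.
#' @param altloc altloc indicator for the produced atoms ('' = none).
#' @param occupancy occupancy for the produced atoms.
#' @param b_factor B factor for the produced atoms.
#' @return A \code{ConformerState} whose atoms are the backbone N/CA/C plus
#'   CB and the templated side chain.
#' @export
build_sidechain <- function(res_type, chis, backbone_frame,
                            altloc = "", occupancy = 1, b_factor = 20) {
  tpl <- SIDECHAIN_TEMPLATES[[res_type]]
  if (is.null(tpl)) stop("residue type not templated: ", res_type)
  n_chi <- length(CHI_TABLE[[res_type]])
  if (length(chis) > n_chi)
    stop("too many chi values for ", res_type)
  chis <- c(chis, rep(180, n_chi - length(chis)))
  pos <- list(N = backbone_frame$N, CA = backbone_frame$CA,
              C = backbone_frame$C)
  pos$CB <- place_atom(pos$C, pos$N, pos$CA, 1.530, 110.5, -122.6)
  for (row in tpl) {
    tor <- row[[5]]
    if (is.character(tor)) {
      m <- regmatches(tor, regexec("^chi([0-9]+)([+-][0-9.]+)?$", tor))[[1]]
      tor <- chis[as.integer(m[2])] +
        if (nzchar(m[3])) as.numeric(m[3]) else 0
    }
    pr <- row[[2]]
    pos[[row[[1]]]] <- place_atom(pos[[pr[1]]], pos[[pr[2]]], pos[[pr[3]]],
                                  row[[3]], row[[4]], tor)
  }
  nm <- names(pos)
  xyz <- do.call(rbind, pos)
  atoms <- new_atom_table(
    name = nm,
    element = vapply(nm, element_of, character(1)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    altloc = rep(altloc, length(nm)),
    occupancy = rep(occupancy, length(nm)),
    b_factor = rep(b_factor, length(nm)),
    is_het = rep(FALSE, length(nm)))
  st <- list(state_id = altloc, atoms = atoms, occupancy = occupancy)
  class(st) <- "ConformerState"
  st
}

# ideal peptide internal coordinates
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8, omega = 180)

build_backbone <- function(n_res, phi = -57, psi = -47) {
  g <- BB_GEOM
  N <- matrix(NA_real_, n_res, 3)
  CA <- matrix(NA_real_, n_res, 3)
  C <- matrix(NA_real_, n_res, 3)
  O <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_res - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_n, g$ang_ca_c_n, psi)
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], g$n_ca,
                              g$ang_c_n_ca, g$omega)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$ca_c,
                             g$ang_n_ca_c, phi)
  }
  for (i in seq_len(n_res)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o,
                         psi + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

residue_from_state <- function(state, extra_atoms, number, chain_id,
                               res_name) {
  atoms <- rbind(state$atoms, extra_atoms)
  new_residue(res_name, number, "", chain_id, atoms)
}

#' Generate a synthetic helical chain with known chi ground truth
#'
#' A helical backbone (phi = -57, psi = -47) carrying templated side chains
#' at assigned or rotamer-sampled chi values. Deterministic per seed.
#'
#' @param n_res number of residues (>= 1).
#' @param residue_types 3-letter codes recycled to length \code{n_res};
#'   default samples from the templated set.
#' @param chi_assignments optional list (length \code{n_res}) of chi
#'   vectors; NULL entries are rotamer-sampled.
#' @param seed integer seed fixing all randomness.
#' @param chain_id chain identifier.
#' @param pdb_id model identifier.
#' @param resolution resolution metadata for the model (A).
#' @return List: \code{model} (a \code{StructureModel}) and \code{truth}
#'   with per-residue \code{types} and true \code{chis}.
#' @export
make_synthetic_chain <- function(n_res, residue_types = NULL,
                                 chi_assignments = NULL, seed = 1,
                                 chain_id = "A", pdb_id = "synt",
                                 resolution = 1.5) {
  stopifnot(n_res >= 1)
  with_seed(seed, {
    if (is.null(residue_types))
      residue_types <- sample(templated_residues(), n_res, replace = TRUE)
    residue_types <- rep(residue_types, length.out = n_res)
    bb <- build_backbone(n_res)
    rotamer_pool <- c(-60, 60, 180)
    chis <- vector("list", n_res)
    residues <- vector("list", n_res)
    for (i in seq_len(n_res)) {
      n_chi <- length(CHI_TABLE[[residue_types[i]]])
      chi_i <- if (!is.null(chi_assignments) && !is.null(chi_assignments[[i]])) {
        chi_assignments[[i]]
      } else {
        sample(rotamer_pool, n_chi, replace = TRUE) +
          stats::runif(n_chi, -10, 10)
      }
      chi_i <- rep(chi_i, length.out = n_chi)
      chi_i <- ((chi_i + 180) %% 360) - 180  # keep truth in (-180, 180]
      chi_i[chi_i == -180] <- 180
      chis[[i]] <- chi_i
      frame <- list(N = bb$N[i, ], CA = bb$CA[i, ], C = bb$C[i, ])
      st <- build_sidechain(residue_types[i], chi_i, frame)
      o_at <- new_atom_table("O", "O", bb$O[i, 1], bb$O[i, 2], bb$O[i, 3],
                             "", 1, 20, FALSE)
      residues[[i]] <- residue_from_state(st, o_at, i, chain_id,
                                          residue_types[i])
    }
    model <- new_structure_model(pdb_id, resolution,
                                 stats::setNames(list(residues), chain_id))
    list(model = model,
         truth = list(types = residue_types, chis = chis, seed = seed))
  })
}

#' Generate a variant partner chain with a known changed fraction
#'
#' Exactly \code{round(f * n_eligible)} eligible residues (templated types
#' with at least one chi) are rebuilt with chi1 rotated by 90-135 degrees
#' (guaranteed a > 30 degree flip-aware change); every other residue's
#' coordinates are copied unchanged.
#'
#' @param fixture output of \code{\link{make_synthetic_chain}} (model +
#'   truth), or a bare \code{StructureModel} built by it.
#' @param change_fraction f in [0, 1].
#' @param seed integer seed.
#' @param pdb_id identifier for the variant model.
#' @return List: \code{model} (the variant \code{StructureModel}) and
#'   \code{truth} with logical \code{changed} labels per residue of the
#'   first chain.
#' @export
make_variant_pair <- function(fixture, change_fraction, seed = 1,
                              pdb_id = "varB") {
  stopifnot(change_fraction >= 0, change_fraction <= 1)
  model <- if (inherits(fixture, "StructureModel")) fixture else fixture$model
  cid <- names(model$chains)[1]
  chain <- model$chains[[cid]]
  n <- length(chain)
  eligible <- which(vapply(chain, function(r) {
    r$is_aa && r$res_name %in% templated_residues() &&
      length(CHI_TABLE[[r$res_name]]) >= 1
  }, logical(1)))
  n_change <- round(change_fraction * length(eligible))
  with_seed(seed, {
    picked <- if (n_change > 0) sort(sample(eligible, n_change)) else integer(0)
    deltas <- stats::runif(length(picked), 90, 135)
    chainB <- chain
    changed <- rep(FALSE, n)
    for (k in seq_along(picked)) {
      i <- picked[k]
      res <- chain[[i]]
      at <- res$atoms
      ds <- measure_chis(at, res$res_name)
      chi_new <- ds$chis
      chi_new[1] <- ((chi_new[1] + deltas[k] + 180) %% 360) - 180
      frame <- list(N = atom_xyz(at, "N"), CA = atom_xyz(at, "CA"),
                    C = atom_xyz(at, "C"))
      st <- build_sidechain(res$res_name, chi_new, frame)
      o_row <- at[at$name == "O", , drop = FALSE]
      chainB[[i]] <- residue_from_state(st, o_row, res$number, cid,
                                        res$res_name)
      changed[i] <- TRUE
    }
    modelB <- new_structure_model(pdb_id, model$resolution,
                                  stats::setNames(list(chainB), cid))
    list(model = modelB,
         truth = list(changed = changed, picked = picked, seed = seed))
  })
}

#' Inject alternate-location states into a model
#'
#' Named residues gain additional conformer states with the requested chi
#' shifts and occupancies; existing side-chain atoms become state 'A' with
#' the first occupancy. The emitted model round-trips through
#' \code{\link{write_pdb}} with valid altloc records.
#'
#' @param model a \code{StructureModel} built from templated residues.
#' @param residue_keys character vector "chain:number" naming residues.
#' @param chi_deltas list (per extra state) of per-chi shift vectors
#'   (recycled over residues), or a single vector for one extra state.
#' @param occupancies occupancy per state including the original as first
#'   element; must sum to <= 1.
#' @return The modified \code{StructureModel}.
#' @export
inject_altlocs <- function(model, residue_keys, chi_deltas, occupancies) {
  if (!is.list(chi_deltas)) chi_deltas <- list(chi_deltas)
  n_states <- length(chi_deltas) + 1L
  if (length(occupancies) != n_states)
    stop("occupancies must have one entry per state (original first)")
  if (sum(occupancies) > 1 + 1e-9)
    stop("occupancies sum to more than 1")
  for (key in residue_keys) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    cid <- parts[1]; num <- as.integer(parts[2])
    chain <- model$chains[[cid]]
    idx <- which(vapply(chain, function(r) r$number == num, logical(1)))
    if (length(idx) == 0) stop("no residue ", key)
    res <- chain[[idx[1]]]
    if (!res$res_name %in% templated_residues())
      stop("cannot inject altloc into untemplated type ", res$res_name)
    at <- res$atoms
    ds <- measure_chis(at, res$res_name)
    frame <- list(N = atom_xyz(at, "N"), CA = atom_xyz(at, "CA"),
                  C = atom_xyz(at, "C"))
    sc_sel <- at$is_sidechain & !at$is_hydrogen
    at$altloc[sc_sel] <- "A"
    at$occupancy[sc_sel] <- occupancies[1]
    new_states <- list()
    state_letters <- LETTERS[seq_len(n_states)]
    for (s in seq_along(chi_deltas)) {
      chi_new <- ds$chis + rep(chi_deltas[[s]], length.out = length(ds$chis))
      chi_new <- ((chi_new + 180) %% 360) - 180
      st <- build_sidechain(res$res_name, chi_new, frame,
                            altloc = state_letters[s + 1],
                            occupancy = occupancies[s + 1])
      sc <- st$atoms[st$atoms$is_sidechain, , drop = FALSE]
      new_states[[s]] <- sc
    }
    res$atoms <- rbind(at, do.call(rbind, new_states))
    chain[[idx[1]]] <- res
    model$chains[[cid]] <- chain
  }
  model
}

#' Render a Gaussian-atom density map for a model
#'
#' \code{rho(x) = sum_atoms occupancy * exp(-|x - r|^2 / (2 sigma^2))} on an
#' orthorhombic grid covering the model's bounding box plus padding, plus
#' optional Gaussian noise, then sigma-normalized. Stands in for a
#' 2Fo-Fc map: a density field correlated with the atoms is all the
#' reliability rule needs. Deterministic per seed.
#'
#' @param model a \code{StructureModel}.
#' @param grid_spacing grid sampling (A), default 0.5.
#' @param atom_sigma Gaussian atom width (A), default 0.8.
#' @param noise_sigma additive noise SD relative to the raw peak of a unit
#'   atom (default 0 = noiseless).
#' @param seed integer seed (noise only).
#' @param padding margin around the bounding box (A); at least
#'   3 * atom_sigma.
#' @param axis_order storage-axis permutation for the emitted map.
#' @return A sigma-normalized \code{DensityMap}.
#' @export
render_density <- function(model, grid_spacing = 0.5, atom_sigma = 0.8,
                           noise_sigma = 0, seed = 1,
                           padding = NULL, axis_order = c(1, 2, 3)) {
  if (is.null(padding)) padding <- max(3 * atom_sigma, 2.5)
  if (padding < 3 * atom_sigma) stop("padding must be >= 3 * atom_sigma")
  ats <- list()
  for (ch in model$chains) for (res in ch) {
    a <- heavy_atoms(res$atoms)
    if (nrow(a)) ats[[length(ats) + 1L]] <- a[, c("x", "y", "z", "occupancy")]
  }
  ats <- do.call(rbind, ats)
  if (is.null(ats) || nrow(ats) == 0) stop("empty model: nothing to render")
  lo <- floor((apply(ats[, 1:3], 2, min) - padding) / grid_spacing)
  hi <- ceiling((apply(ats[, 1:3], 2, max) + padding) / grid_spacing)
  ndim <- as.integer(hi - lo + 1)
  if (any(ndim < 2)) stop("zero-size grid")
  A <- array(0, dim = ndim)
  cutoff <- 4 * atom_sigma
  for (i in seq_len(nrow(ats))) {
    ctr <- as.numeric(ats[i, 1:3])
    occ <- ats$occupancy[i]
    i0 <- pmax(ceiling((ctr - cutoff) / grid_spacing), lo)
    i1 <- pmin(floor((ctr + cutoff) / grid_spacing), hi)
    if (any(i1 < i0)) next
    gx <- exp(-((i0[1]:i1[1]) * grid_spacing - ctr[1])^2 / (2 * atom_sigma^2))
    gy <- exp(-((i0[2]:i1[2]) * grid_spacing - ctr[2])^2 / (2 * atom_sigma^2))
    gz <- exp(-((i0[3]:i1[3]) * grid_spacing - ctr[3])^2 / (2 * atom_sigma^2))
    xi <- (i0[1]:i1[1]) - lo[1] + 1
    yi <- (i0[2]:i1[2]) - lo[2] + 1
    zi <- (i0[3]:i1[3]) - lo[3] + 1
    A[xi, yi, zi] <- A[xi, yi, zi] + occ * (gx %o% gy %o% gz)
  }
  if (noise_sigma > 0) {
    A <- A + with_seed(seed, array(stats::rnorm(length(A), 0, noise_sigma),
                                   dim = dim(A)))
  }
  intervals <- ndim - 1L
  cell <- c(intervals * grid_spacing, 90, 90, 90)
  grid <- aperm(A, axis_order)
  m <- new_density_map(grid, cell, axis_order,
                       start = lo, intervals = intervals)
  normalize_map(m)
}
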