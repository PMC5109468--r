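#' Signed dihedral angle of four points
#'
#' Torsion about the p2-p3 axis with the standard sign convention
#' \code{atan2((n1 x n2) . b2hat, n1 . n2)} where \code{n1 = b1 x b2},
#' \code{n2 = b2 x b3}. Invariant to rigid transforms of all four points.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (A).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-12 || sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("undefined dihedral: collinear or coincident points")
  ang <- atan2(sum(cross3(n1, n2) * (b2 / nb2)), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Circular absolute difference between two angles
#'
#' @param a,b angles in degrees.
#' @return Degrees in [0, 180].
#' @export
angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Flip-aware chi difference
#'
#' For the terminal chi of a chemically symmetric residue (Asp chi2,
#' Glu chi3, Phe chi2, Tyr chi2 and — following the published comparison
#' literally — Arg's last chi when \code{config$flip_arg_terminal}), the
#' difference is the minimum of \code{angle_diff(a, b)} and
#' \code{angle_diff(a, b + 180)}; otherwise plain \code{angle_diff}.
#'
#' @param res_name 3-letter residue type.
#' @param chi_index which chi (1-based).
#' @param a,b the two chi values (degrees).
#' @param config a \code{\link{scvar_config}}.
#' @return Degrees in [0, 180].
#' @export
chi_diff <- function(res_name, chi_index, a, b, config = scvar_config()) {
  n_chi <- length(CHI_TABLE[[res_name]])
  if (is.null(CHI_TABLE[[res_name]]) || chi_index > n_chi)
    stop("invalid chi index ", chi_index, " for ", res_name)
  flip_at <- unname(SYMMETRIC_TERMINAL_CHI[res_name])
  if (!is.na(flip_at) && res_name == "ARG" && !isTRUE(config$flip_arg_terminal))
    flip_at <- NA_integer_
  d <- angle_diff(a, b)
  if (!is.na(flip_at) && chi_index == flip_at &&
      res_name %in% config$symmetric_residues)
    d <- min(d, angle_diff(a, b + 180))
  d
}

#' Measure the chi dihedrals of one conformer state
#'
#' Chi angles follow the standard quadruple table (chi1 = N-CA-CB-Xgamma,
#' numbering outward). A chi whose defining atoms are missing from the state
#' is \code{NA}; Gly/Ala have no chi. Pro's chi2 is measured and reported
#' (type summaries count Pro as one degree of freedom).
#'
#' @param state a \code{ConformerState} (from \code{\link{group_conformers}})
#'   or any atom data.frame carrying the residue's atoms.
#' @param res_name 3-letter residue type.
#' @return List of class \code{DihedralSet}: \code{chis} (numeric, NA where
#'   unmeasurable), \code{n_defined}, plus \code{phi}/\code{psi} slots
#'   (NA here; filled by \code{\link{measure_phi_psi}}).
#' @export
measure_chis <- function(state, res_name) {
  atoms <- if (is.data.frame(state)) state else state$atoms
  quads <- CHI_TABLE[[res_name]]
  if (is.null(quads))
    stop("unknown residue type: ", res_name)
  chis <- rep(NA_real_, length(quads))
  for (i in seq_along(quads)) {
    pts <- lapply(quads[[i]], function(nm) atom_xyz(atoms, nm))
    if (any(vapply(pts, is.null, logical(1)))) next
    chis[i] <- tryCatch(dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
                        error = function(e) NA_real_)
  }
  structure(list(chis = chis, phi = NA_real_, psi = NA_real_,
                 n_defined = sum(!is.na(chis)), res_name = res_name),
            class = "DihedralSet")
}

#' Backbone phi/psi angles along a chain
#'
#' phi is undefined for the first residue, psi for the last. A chain break
#' (C(i)-N(i+1) distance > 2.5 A or missing backbone atoms) makes psi of
#' residue i and phi of residue i+1 undefined.
#'
#' @param chain list of residues (amino acids; others are skipped).
#' @param break_dist_A C-N bond sanity cutoff, default 2.5 A.
#' @return data.frame with \code{seq_id}, \code{res_name}, \code{phi},
#'   \code{psi} (degrees, NA when undefined).
#' @export
measure_phi_psi <- function(chain, break_dist_A = 2.5) {
  chain <- protein_residues(chain)
  n <- length(chain)
  get_bb <- function(res) {
    at <- first_conformer(res)$atoms
    list(N = atom_xyz(at, "N"), CA = atom_xyz(at, "CA"),
         C = atom_xyz(at, "C"))
  }
  bb <- lapply(chain, get_bb)
  bonded <- rep(FALSE, max(n - 1, 0))
  for (i in seq_len(max(n - 1, 0))) {
    Ci <- bb[[i]]$C; Ni1 <- bb[[i + 1]]$N
    bonded[i] <- !is.null(Ci) && !is.null(Ni1) &&
      sqrt(sum((Ci - Ni1)^2)) <= break_dist_A
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    b <- bb[[i]]
    ok_self <- !is.null(b$N) && !is.null(b$CA) && !is.null(b$C)
    if (!ok_self) next
    if (i > 1 && bonded[i - 1] && !is.null(bb[[i - 1]]$C))
      phi[i] <- tryCatch(dihedral(bb[[i - 1]]$C, b$N, b$CA, b$C),
                         error = function(e) NA_real_)
    if (i < n && bonded[i] && !is.null(bb[[i + 1]]$N))
      psi[i] <- tryCatch(dihedral(b$N, b$CA, b$C, bb[[i + 1]]$N),
                         error = function(e) NA_real_)
  }
  data.frame(
    seq_id = vapply(chain, `[[`, character(1), "seq_id"),
    res_name = vapply(chain, `[[`, character(1), "res_name"),
    phi = phi, psi = psi, stringsAsFactors = FALSE
  )
}

#' Compare two dihedral sets under the 30-degree change rule
#'
#' A side-chain conformational change is any shared chi differing by
#' strictly more than \code{config$chi_change_cutoff_deg} (flip-aware for
#' symmetric terminal groups). A chi defined in only one of the two sets is
#' excluded from the comparison; if chi1 is undefined in either, the record
#' is incomparable and excluded from all percentages.
#'
#' @param a,b \code{DihedralSet}s of the same residue type.
#' @param res_name 3-letter residue type.
#' @param config a \code{\link{scvar_config}}.
#' @return List: \code{deltas} (flip-aware per-chi differences, NA where not
#'   shared), \code{same_chi1}, \code{same_chi12}, \code{same_all},
#'   \code{changed}, \code{incomparable}.
#' @export
compare_conformers <- function(a, b, res_name, config = scvar_config()) {
  if (!identical(a$res_name, b$res_name) ||
      (!is.null(a$res_name) && a$res_name != res_name))
    stop("residue type mismatch in conformer comparison")
  nchi <- length(CHI_TABLE[[res_name]])
  cutoff <- config$chi_change_cutoff_deg
  deltas <- rep(NA_real_, nchi)
  for (i in seq_len(nchi)) {
    if (!is.na(a$chis[i]) && !is.na(b$chis[i]))
      deltas[i] <- chi_diff(res_name, i, a$chis[i], b$chis[i], config)
  }
  if (nchi == 0 || is.na(deltas[1])) {
    return(list(deltas = deltas, same_chi1 = NA, same_chi12 = NA,
                same_all = NA, changed = NA, incomparable = TRUE))
  }
  shared <- which(!is.na(deltas))
  same_chi1 <- deltas[1] <= cutoff
  same_chi12 <- same_chi1 &&
    (!(2 %in% shared) || deltas[2] <= cutoff)
  same_all <- all(deltas[shared] <= cutoff)
  list(deltas = deltas, same_chi1 = same_chi1, same_chi12 = same_chi12,
       same_all = same_all, changed = !same_all, incomparable = FALSE)
}
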