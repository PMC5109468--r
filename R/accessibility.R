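#' @title Solvent accessibility (Shrake-Rupley)
#' @description Accessible surface areas are computed on the whole
#' structure (all chains jointly, as NACCESS does) and then attributed per
#' chain/residue, using the first conformer of altloc residues and
#' excluding hydrogens. Waters and ligands are excluded from occlusion by
#' default (\code{config$include_het_in_occlusion} to change).
#' @name accessibility
NULL

# deterministic quasi-uniform unit-sphere points (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi_g <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- phi_g * (i - 0.5)
  cbind(r * cos(th), r * sin(th), z)
}

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  bad <- is.na(r)
  if (any(bad)) {
    message("unknown element(s) ", paste(unique(element[bad]), collapse = ","),
            "; using default vdW radius ", VDW_DEFAULT)
    r[bad] <- VDW_DEFAULT
  }
  unname(r)
}

# flatten a model to the heavy-atom table used for SASA: first conformer
# per residue, hydrogens out, one row per atom, with residue bookkeeping
sasa_atom_table <- function(model, config) {
  rows <- list()
  for (cid in names(model$chains)) {
    for (ri in seq_along(model$chains[[cid]])) {
      res <- model$chains[[cid]][[ri]]
      if (!res$is_aa && !isTRUE(config$include_het_in_occlusion)) next
      at <- heavy_atoms(first_conformer(res)$atoms)
      if (nrow(at) == 0) next
      at$chain <- cid
      at$res_index <- ri
      at$res_name <- res$res_name
      at$seq_id <- res$seq_id
      at$resnum <- res$number
      at$is_protein <- res$is_aa
      rows[[length(rows) + 1L]] <- at
    }
  }
  if (length(rows) == 0) stop("empty model: no heavy atoms for SASA")
  do.call(rbind, rows)
}

#' Per-atom accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere of radius \code{r_vdw + probe} is sampled with
#' \code{n_points} quasi-uniform test points; the accessible fraction is
#' the fraction not inside any other atom's expanded sphere. Area =
#' \code{4 pi (r + p)^2 * accessible fraction}.
#'
#' @param model a \code{StructureModel} (all chains are used jointly).
#' @param probe_radius probe radius in A (water, 1.4).
#' @param n_points test points per atom (960).
#' @param config a \code{\link{scvar_config}}.
#' @return data.frame with one row per heavy atom: chain, resnum, seq_id,
#'   res_name, name, element, asa (A^2).
#' @export
shrake_rupley <- function(model, probe_radius = NULL, n_points = NULL,
                          config = scvar_config()) {
  if (is.null(probe_radius)) probe_radius <- config$probe_radius_A
  if (is.null(n_points)) n_points <- config$sasa_n_points
  at <- sasa_atom_table(model, config)
  n <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- vdw_radius(at$element) + probe_radius
  sp <- sphere_points(n_points)
  asa <- numeric(n)
  rmax <- max(rad)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < rad[i] + rmax & di > 1e-9)
    pts <- sp * rad[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (pts[acc, 1] - xyz[j, 1])^2 + (pts[acc, 2] - xyz[j, 2])^2 +
        (pts[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj >= rad[j]^2
    }
    asa[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  out <- at[, c("chain", "resnum", "seq_id", "res_name", "name", "element")]
  out$asa <- asa
  rownames(out) <- NULL
  out
}

#' Per-residue exposure records
#'
#' Absolute ASA is the sum over the residue's heavy atoms; relative ASA
#' divides by the Gly-X-Gly reference maximum for the residue type. A
#' residue is exposed when absolute ASA >= \code{exposure_asa_cutoff_A2}
#' (1.0 A^2); the classifier uses absolute ASA.
#'
#' @param model a \code{StructureModel}.
#' @param config a \code{\link{scvar_config}}.
#' @param atom_asa optional precomputed result of \code{\link{shrake_rupley}}.
#' @return data.frame of \code{ExposureRecord}s: chain, resnum, seq_id,
#'   res_name, absolute_asa, relative_asa, exposed.
#' @export
residue_asa <- function(model, config = scvar_config(), atom_asa = NULL) {
  if (is.null(atom_asa)) atom_asa <- shrake_rupley(model, config = config)
  key <- paste(atom_asa$chain, atom_asa$seq_id, sep = "\r")
  agg <- tapply(atom_asa$asa, key, sum)
  first <- !duplicated(key)
  out <- atom_asa[first, c("chain", "resnum", "seq_id", "res_name")]
  out$absolute_asa <- as.numeric(agg[key[first]])
  ref <- REF_ASA[out$res_name]
  out$relative_asa <- out$absolute_asa / unname(ref)
  out$exposed <- out$absolute_asa >= config$exposure_asa_cutoff_A2
  rownames(out) <- NULL
  out
}

#' Classify a residue as buried or exposed
#'
#' @param record one \code{ExposureRecord} row (needs \code{absolute_asa}).
#' @param config a \code{\link{scvar_config}}.
#' @return \code{"exposed"} or \code{"buried"}.
#' @export
classify_exposure <- function(record, config = scvar_config()) {
  if (record$absolute_asa[1] >= config$exposure_asa_cutoff_A2) "exposed"
  else "buried"
}
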