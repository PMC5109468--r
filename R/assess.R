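#' Build a multi-conformer native ensemble
#'
#' Collects, per residue of the reference (first) native chain, every
#' alternate-location conformer state from every supplied native source —
#' never only state 'A'. When density maps are supplied, residues whose
#' side chain is unreliable in every source are excluded from assessment.
#'
#' @param native_models list of \code{StructureModel}s of the same protein
#'   (the first is the reference; others are paired by global alignment).
#' @param maps optional list of normalized \code{DensityMap}s parallel to
#'   \code{native_models} (NULL entries allowed).
#' @param config a \code{\link{scvar_config}}.
#' @return List of class \code{NativeEnsemble}: \code{reference} chain,
#'   \code{entries} — per reference residue a list with \code{res_name},
#'   \code{seq_id}, \code{conformers} (each: chis, provenance, state_id,
#'   reliable), and \code{excluded_unreliable}.
#' @export
build_ensemble <- function(native_models, maps = NULL,
                           config = scvar_config()) {
  if (length(native_models) == 0) stop("no native models supplied")
  ref_model <- native_models[[1]]
  ref_cid <- names(ref_model$chains)[1]
  ref <- protein_residues(ref_model$chains[[ref_cid]])
  entries <- lapply(ref, function(res) {
    list(res_name = res$res_name, seq_id = res$seq_id, conformers = list(),
         excluded_unreliable = FALSE)
  })
  for (m in seq_along(native_models)) {
    model <- native_models[[m]]
    map <- if (!is.null(maps) && length(maps) >= m) maps[[m]] else NULL
    for (cid in names(model$chains)) {
      chain <- protein_residues(model$chains[[cid]])
      if (m == 1 && cid == ref_cid) {
        pairing <- data.frame(i = seq_along(ref), j = seq_along(ref),
                              type_mismatch = FALSE)
      } else {
        pairing <- pair_residues(ref, chain, config = config)
      }
      for (k in seq_len(nrow(pairing))) {
        if (pairing$type_mismatch[k]) next
        i <- pairing$i[k]
        res <- chain[[pairing$j[k]]]
        if (res$res_name != entries[[i]]$res_name) next
        rel <- NA
        if (!is.null(map)) {
          rel <- residue_reliability(map, res, config)$residue_reliable_sidechain
        }
        for (st in group_conformers(res)) {
          ds <- measure_chis(st, res$res_name)
          entries[[i]]$conformers[[length(entries[[i]]$conformers) + 1L]] <-
            list(chis = ds$chis, provenance = sprintf("%s:%s:%d", model$pdb_id,
                                                      cid, res$number),
                 state_id = st$state_id, reliable = rel)
        }
      }
    }
  }
  if (!is.null(maps)) {
    for (i in seq_along(entries)) {
      rels <- vapply(entries[[i]]$conformers, function(cf)
        isTRUE(cf$reliable), logical(1))
      known <- vapply(entries[[i]]$conformers, function(cf)
        !is.na(cf$reliable), logical(1))
      if (length(rels) && all(known) && !any(rels))
        entries[[i]]$excluded_unreliable <- TRUE
    }
  }
  structure(list(reference = ref, entries = entries), class = "NativeEnsemble")
}

# max flip-aware chi difference over shared defined chis (Inf if none)
minimax_delta <- function(pred_chis, nat_chis, res_name, config) {
  shared <- which(!is.na(pred_chis) & !is.na(nat_chis))
  if (length(shared) == 0) return(list(max = Inf, deltas = NULL))
  d <- vapply(shared, function(i)
    chi_diff(res_name, i, pred_chis[i], nat_chis[i], config), numeric(1))
  deltas <- rep(NA_real_, length(pred_chis))
  deltas[shared] <- d
  list(max = max(d), deltas = deltas)
}

#' Closest native conformer to a prediction
#'
#' The nearest conformer minimizes the maximum flip-aware per-chi
#' difference; ties break toward the smaller chi1 difference, then toward
#' earlier provenance order. (\code{config$closest_metric = "chi1_lex"}
#' sorts lexicographically by (delta chi1, delta chi2, ...) instead.)
#'
#' @param pred_chis the predicted residue's chi vector.
#' @param entry one ensemble entry (from \code{\link{build_ensemble}}).
#' @param config a \code{\link{scvar_config}}.
#' @return List: \code{index}, \code{conformer}, \code{deltas} (per-chi,
#'   flip-aware); or NULL when the entry has no conformers.
#' @export
closest_conformer <- function(pred_chis, entry, config = scvar_config()) {
  cfs <- entry$conformers
  if (length(cfs) == 0) return(NULL)
  res_name <- entry$res_name
  stats_ <- lapply(cfs, function(cf)
    minimax_delta(pred_chis, cf$chis, res_name, config))
  maxes <- vapply(stats_, `[[`, numeric(1), "max")
  d1 <- vapply(stats_, function(s)
    if (!is.null(s$deltas) && !is.na(s$deltas[1])) s$deltas[1] else Inf,
    numeric(1))
  if (identical(config$closest_metric, "chi1_lex")) {
    ord <- order(d1, maxes)
  } else {
    ord <- order(maxes, d1)
  }
  best <- ord[1]
  list(index = best, conformer = cfs[[best]], deltas = stats_[[best]]$deltas)
}

#' Chi accuracy of a side-chain prediction against a native ensemble
#'
#' Each predicted residue is scored against its closest native conformer:
#' correct at chi1 iff the flip-aware delta chi1 <= 30 degrees, at chi1+2
#' iff chi1 and chi2 both, at chi_all iff every shared chi. Gly/Ala are
#' excluded; residues excluded as density-unreliable are dropped
#' (\code{n_excluded}); residues absent from the prediction count as
#' incorrect and are also reported separately (\code{n_missing}).
#'
#' @param prediction_model a \code{StructureModel} (first chain is scored).
#' @param ensemble a \code{NativeEnsemble}.
#' @param config a \code{\link{scvar_config}}.
#' @return List of class \code{AccuracyReport}: \code{n_assessed},
#'   \code{n_excluded}, \code{n_missing}, \code{chi1_pct},
#'   \code{chi12_pct}, \code{chi_all_pct}, \code{detail} (per-residue
#'   data.frame).
#' @export
chi_accuracy <- function(prediction_model, ensemble,
                         config = scvar_config()) {
  pred_chain <- protein_residues(
    prediction_model$chains[[names(prediction_model$chains)[1]]])
  pairing <- pair_residues(ensemble$reference, pred_chain, config = config)
  pred_of <- integer(length(ensemble$entries))
  pred_of[] <- NA_integer_
  pred_of[pairing$i[!pairing$type_mismatch]] <-
    pairing$j[!pairing$type_mismatch]
  cutoff <- config$chi_change_cutoff_deg
  rows <- list()
  n_excluded <- 0L
  for (i in seq_along(ensemble$entries)) {
    entry <- ensemble$entries[[i]]
    if (entry$res_name %in% c("GLY", "ALA")) next
    if (length(entry$conformers) == 0) { n_excluded <- n_excluded + 1L; next }
    if (isTRUE(entry$excluded_unreliable)) { n_excluded <- n_excluded + 1L; next }
    nat_has_chi1 <- any(vapply(entry$conformers, function(cf)
      !is.na(cf$chis[1]), logical(1)))
    if (!nat_has_chi1) { n_excluded <- n_excluded + 1L; next }
    j <- pred_of[i]
    if (is.na(j)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = entry$seq_id, res_name = entry$res_name, missing = TRUE,
        chi1_ok = FALSE, chi12_ok = FALSE, chi_all_ok = FALSE,
        delta_chi1 = NA_real_, closest = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    pres <- pred_chain[[j]]
    pchis <- measure_chis(first_conformer(pres)$atoms, pres$res_name)$chis
    if (is.na(pchis[1])) {
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = entry$seq_id, res_name = entry$res_name, missing = TRUE,
        chi1_ok = FALSE, chi12_ok = FALSE, chi_all_ok = FALSE,
        delta_chi1 = NA_real_, closest = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    cc <- closest_conformer(pchis, entry, config)
    d <- cc$deltas
    shared <- which(!is.na(d))
    chi1_ok <- !is.na(d[1]) && d[1] <= cutoff
    chi12_ok <- chi1_ok && (!(2 %in% shared) || d[2] <= cutoff)
    chi_all_ok <- length(shared) > 0 && all(d[shared] <= cutoff)
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = entry$seq_id, res_name = entry$res_name, missing = FALSE,
      chi1_ok = chi1_ok, chi12_ok = chi12_ok, chi_all_ok = chi_all_ok,
      delta_chi1 = d[1], closest = cc$conformer$provenance,
      stringsAsFactors = FALSE)
  }
  detail <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(), res_name = character(),
               missing = logical(), chi1_ok = logical(),
               chi12_ok = logical(), chi_all_ok = logical(),
               delta_chi1 = numeric(), closest = character())
  n <- nrow(detail)
  pct <- function(x) if (n == 0) NA_real_ else 100 * sum(x) / n
  structure(list(
    n_assessed = n, n_excluded = n_excluded,
    n_missing = sum(detail$missing),
    chi1_pct = pct(detail$chi1_ok),
    chi12_pct = pct(detail$chi12_ok),
    chi_all_pct = pct(detail$chi_all_ok),
    detail = detail
  ), class = "AccuracyReport")
}

#' @export
print.AccuracyReport <- function(x, ...) {
  cat(sprintf(
    "AccuracyReport: n=%d (excluded %d, missing %d)  chi1 %.1f%%  chi1+2 %.1f%%  chi_all %.1f%%\n",
    x$n_assessed, x$n_excluded, x$n_missing,
    x$chi1_pct, x$chi12_pct, x$chi_all_pct))
  invisible(x)
}

#' Density-sum score of a predicted model
#'
#' Sum of interpolated point densities (sigma units) at the predicted
#' side-chain heavy-atom coordinates (first predicted conformer); atoms
#' outside the map contribute 0 with a warning. Higher is better: a model
#' whose side chains sit in observed density outscores one displaced out
#' of it.
#'
#' @param prediction_model a \code{StructureModel}.
#' @param map a normalized \code{DensityMap}.
#' @param config a \code{\link{scvar_config}}.
#' @param sidechain_only sum side-chain heavy atoms only (default TRUE).
#' @return List: \code{total} (sigma sum), \code{per_residue} data.frame.
#' @export
density_sum_score <- function(prediction_model, map,
                              config = scvar_config(),
                              sidechain_only = TRUE) {
  if (!isTRUE(map$normalized)) stop("map must be sigma-normalized")
  rows <- list()
  total <- 0
  n_atoms <- 0L
  for (cid in names(prediction_model$chains)) {
    for (res in protein_residues(prediction_model$chains[[cid]])) {
      at <- heavy_atoms(first_conformer(res)$atoms)
      if (sidechain_only) at <- at[at$is_sidechain, , drop = FALSE]
      if (nrow(at) == 0) next
      s <- 0
      for (i in seq_len(nrow(at))) {
        s <- s + tryCatch(point_density(map, c(at$x[i], at$y[i], at$z[i])),
                          error = function(e) {
                            warning("predicted atom outside map: contributes 0",
                                    call. = FALSE)
                            0
                          })
      }
      n_atoms <- n_atoms + nrow(at)
      total <- total + s
      rows[[length(rows) + 1L]] <- data.frame(
        chain = cid, seq_id = res$seq_id, res_name = res$res_name,
        n_atoms = nrow(at), density_sum = s, stringsAsFactors = FALSE)
    }
  }
  if (n_atoms == 0L) {
    warning("no side-chain atoms to score; density sum is 0")
    return(list(total = 0, per_residue = NULL))
  }
  list(total = total, per_residue = do.call(rbind, rows))
}
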