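#' Global sequence alignment with percent identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10 / extend 0.5,
#' via Biostrings). Identity = identical aligned positions / aligned
#' columns excluding terminal gaps.
#'
#' @param s1,s2 one-letter amino-acid strings (non-empty).
#' @param config a \code{\link{scvar_config}} (gap penalties).
#' @return List: \code{aligned1}, \code{aligned2} (gapped strings),
#'   \code{identity_pct}, \code{score}.
#' @export
align_sequences <- function(s1, s2, config = scvar_config()) {
  if (!nzchar(s1) || !nzchar(s2)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s1), Biostrings::AAString(s2),
    substitutionMatrix = "BLOSUM62",
    gapOpening = config$gap_open, gapExtension = config$gap_extend,
    type = "global")
  a1 <- as.character(Biostrings::alignedPattern(pa))
  a2 <- as.character(Biostrings::alignedSubject(pa))
  v1 <- strsplit(a1, "")[[1]]
  v2 <- strsplit(a2, "")[[1]]
  ncol_aln <- length(v1)
  nongap <- which(v1 != "-" & v2 != "-")
  # terminal-gap columns: before the first and after the last position at
  # which both sequences have started/not yet ended
  first1 <- min(which(v1 != "-")); last1 <- max(which(v1 != "-"))
  first2 <- min(which(v2 != "-")); last2 <- max(which(v2 != "-"))
  core <- seq(max(first1, first2), min(last1, last2))
  ident <- sum(v1[core] == v2[core] & v1[core] != "-")
  list(aligned1 = a1, aligned2 = a2,
       identity_pct = 100 * ident / length(core),
       score = Biostrings::score(pa))
}

#' Match residues of two chains through an alignment
#'
#' Only columns with residues on both sides produce a pair; columns whose
#' residue types differ are kept but flagged \code{type_mismatch} (they are
#' excluded from chi comparison and counted separately for mutation
#' analyses).
#'
#' @param chainA,chainB residue lists.
#' @param alignment output of \code{\link{align_sequences}} on the two
#'   chain sequences; computed here when NULL.
#' @param config a \code{\link{scvar_config}}.
#' @return data.frame: \code{i}, \code{j} (1-based indices into the protein
#'   residues of each chain), \code{type_mismatch}.
#' @export
pair_residues <- function(chainA, chainB, alignment = NULL,
                          config = scvar_config()) {
  if (is.null(alignment))
    alignment <- align_sequences(chain_sequence(chainA),
                                 chain_sequence(chainB), config)
  v1 <- strsplit(alignment$aligned1, "")[[1]]
  v2 <- strsplit(alignment$aligned2, "")[[1]]
  i <- cumsum(v1 != "-")
  j <- cumsum(v2 != "-")
  both <- which(v1 != "-" & v2 != "-")
  data.frame(i = i[both], j = j[both],
             type_mismatch = v1[both] != v2[both])
}

hamming4 <- function(a, b) {
  va <- strsplit(tolower(a), "")[[1]]
  vb <- strsplit(tolower(b), "")[[1]]
  n <- max(length(va), length(vb))
  length(va) <- n; length(vb) <- n
  sum(va != vb | is.na(va) | is.na(vb))
}

#' Curate a chain pair for the variation survey
#'
#' Accepts a pair iff sequence identity, TM-score, Ca RMSD, resolution,
#' and chain length all pass the configured cutoffs, and the PDB-id rule
#' matches the mode: same-crystal pairs come from one PDB entry (different
#' chains), cross-crystal pairs from entries whose 4-character ids differ
#' in more than two positions.
#'
#' @param modelA,modelB \code{StructureModel}s with resolution metadata.
#' @param chainA_id,chainB_id chain identifiers within each model.
#' @param mode \code{"same-crystal"} or \code{"cross-crystal"}.
#' @param config a \code{\link{scvar_config}}.
#' @return List: \code{accept}, \code{reasons} (character, empty when
#'   accepted), \code{identity_pct}, \code{superposition}, \code{pairing}.
#' @export
curate_pair <- function(modelA, modelB, chainA_id = NULL, chainB_id = NULL,
                        mode = c("same-crystal", "cross-crystal"),
                        config = scvar_config()) {
  mode <- match.arg(mode)
  if (is.null(chainA_id)) chainA_id <- names(modelA$chains)[1]
  if (is.null(chainB_id)) chainB_id <- names(modelB$chains)[if (identical(modelA$pdb_id, modelB$pdb_id) && length(modelB$chains) > 1) 2 else 1]
  chA <- modelA$chains[[chainA_id]]
  chB <- modelB$chains[[chainB_id]]
  reasons <- character(0)
  if (is.na(modelA$resolution) || is.na(modelB$resolution)) {
    reasons <- c(reasons, "resolution-missing")
  } else if (modelA$resolution > config$resolution_max_A ||
             modelB$resolution > config$resolution_max_A) {
    reasons <- c(reasons, "resolution")
  }
  lenA <- length(protein_residues(chA))
  lenB <- length(protein_residues(chB))
  if (min(lenA, lenB) <= config$min_length_aa)
    reasons <- c(reasons, "length")
  if (mode == "same-crystal") {
    if (!identical(modelA$pdb_id, modelB$pdb_id) ||
        identical(chainA_id, chainB_id))
      reasons <- c(reasons, "pdb-id")
  } else {
    if (hamming4(modelA$pdb_id, modelB$pdb_id) <= 2)
      reasons <- c(reasons, "pdb-id")
  }
  aln <- align_sequences(chain_sequence(chA), chain_sequence(chB), config)
  if (aln$identity_pct <= config$pair_identity_min_pct)
    reasons <- c(reasons, "identity")
  pairing <- pair_residues(chA, chB, aln, config)
  sup <- NULL
  if (nrow(pairing) >= 3) {
    sup <- tm_score(chA, chB, pairing)
    if (sup$tm_score <= config$tm_cutoff) reasons <- c(reasons, "tm")
    if (sup$rmsd >= config$rmsd_cutoff_A) reasons <- c(reasons, "rmsd")
  } else {
    reasons <- c(reasons, "pairing")
  }
  list(accept = length(reasons) == 0, reasons = reasons,
       identity_pct = aln$identity_pct, superposition = sup,
       pairing = pairing)
}

#' Conformational variation across a residue's altloc states
#'
#' All unordered pairs of conformer states are compared; the residue keeps
#' chi1 iff every pair keeps chi1 (likewise chi1+2 and chi_all) and is
#' changed iff any pair changed.
#'
#' @param residue a residue with >= 2 conformer states and measurable chi1.
#' @param config a \code{\link{scvar_config}}.
#' @return One-row data.frame \code{ComparisonRecord}: kind = "altloc",
#'   n_states, keeps_chi1/keeps_chi12/keeps_all, changed, incomparable,
#'   max_delta; or NULL for residues without multiple states.
#' @export
altloc_variation <- function(residue, config = scvar_config()) {
  if (!residue$is_standard) return(NULL)
  states <- group_conformers(residue)
  if (length(states) < 2) return(NULL)
  sets <- lapply(states, measure_chis, res_name = residue$res_name)
  keeps <- c(chi1 = TRUE, chi12 = TRUE, all = TRUE)
  any_comparable <- FALSE
  max_delta <- 0
  for (a in seq_len(length(sets) - 1)) for (b in seq(a + 1, length(sets))) {
    cmp <- compare_conformers(sets[[a]], sets[[b]], residue$res_name, config)
    if (isTRUE(cmp$incomparable)) next
    any_comparable <- TRUE
    keeps["chi1"] <- keeps["chi1"] && cmp$same_chi1
    keeps["chi12"] <- keeps["chi12"] && cmp$same_chi12
    keeps["all"] <- keeps["all"] && cmp$same_all
    max_delta <- max(max_delta, cmp$deltas, na.rm = TRUE)
  }
  if (!any_comparable) {
    return(data.frame(kind = "altloc", chain = residue$chain_id,
                      seq_id = residue$seq_id, res_name = residue$res_name,
                      n_states = length(states),
                      keeps_chi1 = NA, keeps_chi12 = NA, keeps_all = NA,
                      changed = NA, incomparable = TRUE, max_delta = NA_real_,
                      stringsAsFactors = FALSE))
  }
  data.frame(kind = "altloc", chain = residue$chain_id,
             seq_id = residue$seq_id, res_name = residue$res_name,
             n_states = length(states),
             keeps_chi1 = unname(keeps["chi1"]),
             keeps_chi12 = unname(keeps["chi12"]),
             keeps_all = unname(keeps["all"]),
             changed = !unname(keeps["all"]),
             incomparable = FALSE, max_delta = max_delta,
             stringsAsFactors = FALSE)
}

#' Per-residue variation records for a curated chain pair
#'
#' One \code{ComparisonRecord} per compared residue pair: flip-aware chi
#' categories under the 30-degree rule plus backbone change (delta phi or
#' delta psi > 30 degrees). Residues with alternate locations in either
#' partner, with reliability known false, with mismatched types, or with
#' chi1 undefined are excluded (the published same-crystal protocol).
#'
#' @param chainA,chainB residue lists.
#' @param pairing data.frame from \code{\link{pair_residues}}.
#' @param config a \code{\link{scvar_config}}.
#' @param reliableA,reliableB optional logical vectors (per protein residue
#'   of each chain): side-chain density reliability; FALSE excludes.
#' @param exposureA,exposureB optional \code{\link{residue_asa}} tables.
#' @return data.frame of records: seq_id, res_name, same_chi1, same_chi12,
#'   same_all, changed, backbone_changed, delta_chi1, exposedA, exposedB.
#' @export
pair_variation <- function(chainA, chainB, pairing = NULL,
                           config = scvar_config(),
                           reliableA = NULL, reliableB = NULL,
                           exposureA = NULL, exposureB = NULL) {
  protA <- protein_residues(chainA)
  protB <- protein_residues(chainB)
  if (is.null(pairing)) pair <- pair_residues(chainA, chainB, config = config)
  else pair <- pairing
  ppA <- measure_phi_psi(chainA)
  ppB <- measure_phi_psi(chainB)
  expo_of <- function(tbl, res) {
    if (is.null(tbl)) return(NA)
    hit <- tbl$exposed[tbl$chain == res$chain_id & tbl$seq_id == res$seq_id]
    if (length(hit)) hit[1] else NA
  }
  rows <- list()
  for (k in seq_len(nrow(pair))) {
    i <- pair$i[k]; j <- pair$j[k]
    resA <- protA[[i]]; resB <- protB[[j]]
    if (pair$type_mismatch[k]) next
    if (!resA$is_standard || !resB$is_standard) next
    if (resA$res_name %in% c("GLY", "ALA")) next
    if (length(group_conformers(resA)) > 1 ||
        length(group_conformers(resB)) > 1) next
    if (!is.null(reliableA) && isFALSE(reliableA[i])) next
    if (!is.null(reliableB) && isFALSE(reliableB[j])) next
    dsA <- measure_chis(first_conformer(resA)$atoms, resA$res_name)
    dsB <- measure_chis(first_conformer(resB)$atoms, resB$res_name)
    cmp <- compare_conformers(dsA, dsB, resA$res_name, config)
    if (isTRUE(cmp$incomparable)) next
    dphi <- angle_diff(ppA$phi[i], ppB$phi[j])
    dpsi <- angle_diff(ppA$psi[i], ppB$psi[j])
    backbone_changed <- if (is.na(ppA$phi[i]) || is.na(ppB$phi[j]) ||
                            is.na(ppA$psi[i]) || is.na(ppB$psi[j])) NA
    else (dphi > config$backbone_change_cutoff_deg ||
          dpsi > config$backbone_change_cutoff_deg)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "pair", seq_id = resA$seq_id, res_name = resA$res_name,
      same_chi1 = cmp$same_chi1, same_chi12 = cmp$same_chi12,
      same_all = cmp$same_all, changed = cmp$changed,
      backbone_changed = backbone_changed,
      delta_chi1 = cmp$deltas[1],
      exposedA = expo_of(exposureA, resA), exposedB = expo_of(exposureB, resB),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

resolution_bin <- function(res) {
  cut(res, breaks = c(0, 1, 2, 3, 3.5),
      labels = c("<1.0", "1.0-2.0", "2.0-3.0", "3.0-3.5"),
      right = FALSE, include.lowest = TRUE)
}

#' Aggregate variation records into a survey table
#'
#' Percentages are computed per structure first, then averaged (mean +/-
#' SD across structures) within each grouping cell. This is not the same
#' as pooling residues across structures; the per-structure convention is
#' the published one. SD is population SD by default.
#'
#' @param records data.frame of comparison records; must carry
#'   \code{structure_id} and \code{resolution} columns (add them when
#'   collecting records across structures) plus the category flags.
#' @param grouping \code{"resolution"}, \code{"res_name"} or
#'   \code{"exposure"}.
#' @param config a \code{\link{scvar_config}}.
#' @return data.frame \code{SurveyTable}: group, n_structures, n_records,
#'   and mean/sd of pct_same_chi1, pct_same_chi12, pct_same_all,
#'   pct_changed.
#' @export
aggregate_survey <- function(records, grouping = c("resolution", "res_name",
                                                   "exposure"),
                             config = scvar_config()) {
  grouping <- match.arg(grouping)
  if (is.null(records) || nrow(records) == 0) stop("no records to aggregate")
  records <- records[!is.na(records$changed), , drop = FALSE]
  grp <- switch(grouping,
    resolution = as.character(resolution_bin(records$resolution)),
    res_name = records$res_name,
    exposure = ifelse(records$exposedA, "exposed", "buried"))
  sdf <- function(x) {
    if (identical(config$sd_type, "sample")) stats::sd(x)
    else sqrt(mean((x - mean(x))^2))
  }
  out <- list()
  for (g in unique(grp[!is.na(grp)])) {
    sel <- which(grp == g)
    per_struct <- split(seq_along(sel), records$structure_id[sel])
    pct <- function(flag) vapply(per_struct, function(ii) {
      100 * mean(flag[sel][ii])
    }, numeric(1))
    p1 <- pct(records$same_chi1); p12 <- pct(records$same_chi12)
    pa <- pct(records$same_all); pc <- pct(records$changed)
    out[[length(out) + 1L]] <- data.frame(
      group = g, n_structures = length(per_struct), n_records = length(sel),
      pct_same_chi1 = mean(p1), sd_same_chi1 = sdf(p1),
      pct_same_chi12 = mean(p12), sd_same_chi12 = sdf(p12),
      pct_same_all = mean(pa), sd_same_all = sdf(pa),
      pct_changed = mean(pc), sd_changed = sdf(pc),
      stringsAsFactors = FALSE)
  }
  tbl <- do.call(rbind, out)
  rownames(tbl) <- NULL
  tbl
}

#' Residue flexibility estimate
#'
#' \code{estimate = pct_altloc + (100 - pct_certain_residues)
#' [+ pct_cross_structure_changed]}: the fraction of residues flexible
#' either as multi-state alternate locations or as density-uncertain
#' conformations, optionally adding the cross-structure changed fraction.
#'
#' @param pct_altloc percent of residues with alternate locations.
#' @param pct_certain_residues percent of density-certain residues.
#' @param pct_cross_structure_changed optional percent of residues changing
#'   conformation across chains/crystals.
#' @return The estimate in percent.
#' @examples
#' flexibility_estimate(12, 95)      # 17
#' flexibility_estimate(3, 87)       # 16
#' flexibility_estimate(12, 95, 3)   # 20
#' @export
flexibility_estimate <- function(pct_altloc, pct_certain_residues,
                                 pct_cross_structure_changed = NULL) {
  vals <- c(pct_altloc, pct_certain_residues, pct_cross_structure_changed)
  if (any(vals < 0 | vals > 100))
    stop("percentages must be within [0, 100]")
  est <- pct_altloc + (100 - pct_certain_residues)
  if (!is.null(pct_cross_structure_changed))
    est <- est + pct_cross_structure_changed
  est
}
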