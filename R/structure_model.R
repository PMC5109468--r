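#' @title Structure data model
#' @description
#' A \code{StructureModel} is a plain list: \code{pdb_id}, \code{resolution}
#' (A, or NA), and \code{chains}, a named list mapping chain id to an ordered
#' list of residues. Each residue is a list with \code{res_name} (3-letter,
#' after HETATM-parent mapping), \code{number}, \code{icode}, \code{seq_id}
#' (number + insertion code, the comparison key), \code{chain_id},
#' \code{is_aa} / \code{is_standard} flags, and \code{atoms}, a data.frame
#' with one row per atom record: \code{name, element, x, y, z, altloc,
#' occupancy, b_factor, is_sidechain, is_hydrogen, is_het}.
#' @name StructureModel
NULL

new_atom_table <- function(name = character(), element = character(),
                           x = numeric(), y = numeric(), z = numeric(),
                           altloc = character(), occupancy = numeric(),
                           b_factor = numeric(), is_het = logical()) {
  df <- data.frame(
    name = name, element = element, x = x, y = y, z = z,
    altloc = altloc, occupancy = occupancy, b_factor = b_factor,
    is_het = is_het, stringsAsFactors = FALSE
  )
  df$is_hydrogen <- df$element %in% c("H", "D")
  df$is_sidechain <- !(df$name %in% BACKBONE_ATOMS)
  df
}

new_residue <- function(res_name, number, icode, chain_id, atoms,
                        is_het = FALSE) {
  parent <- unname(HET_PARENT[res_name])
  mapped <- !is.na(parent)
  std_name <- if (mapped) parent else res_name
  structure(list(
    res_name = std_name,
    orig_name = res_name,
    number = number,
    icode = icode,
    seq_id = paste0(number, icode),
    chain_id = chain_id,
    is_standard = std_name %in% names(AA3TO1),
    # nonstandard ATOM-record residues with a CA still count as amino acids
    # (sequence letter 'X'); HETATM waters/ligands are excluded
    is_aa = std_name %in% names(AA3TO1) ||
      (!isTRUE(is_het) && "CA" %in% atoms$name),
    het_mapped = mapped,
    atoms = atoms
  ), class = "scvar_residue")
}

new_structure_model <- function(pdb_id = "xxxx", resolution = NA_real_,
                                chains = list()) {
  if (!is.na(resolution) && resolution <= 0)
    stop("resolution must be positive when present")
  structure(list(pdb_id = pdb_id, resolution = resolution, chains = chains),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  nres <- vapply(x$chains, length, integer(1))
  cat(sprintf("StructureModel %s  resolution %s A  %d chain(s): %s\n",
              x$pdb_id,
              ifelse(is.na(x$resolution), "NA", format(x$resolution)),
              length(x$chains),
              paste(sprintf("%s(%d)", names(x$chains), nres), collapse = " ")))
  invisible(x)
}

residue_is_protein <- function(res) isTRUE(res$is_aa)

#' Heavy (non-hydrogen) atoms of a residue or conformer state
#' @param atoms an atom data.frame.
#' @return The subset of rows that are not hydrogens.
#' @keywords internal
heavy_atoms <- function(atoms) atoms[!atoms$is_hydrogen, , drop = FALSE]

#' Group a residue's atoms into alternate-location conformer states
#'
#' One state is produced per distinct non-blank altloc indicator; atoms with
#' a blank indicator are shared into every state. A residue whose atoms all
#' carry blank indicators yields a single state with occupancy 1. States are
#' ordered by indicator. The representative occupancy of a state is the
#' modal occupancy of its own (non-shared) side-chain atoms; a disagreement
#' between them is logged, never fatal.
#'
#' @param residue a residue from a \code{StructureModel}.
#' @return List of \code{ConformerState}: \code{state_id}, \code{atoms},
#'   \code{occupancy}.
#' @export
group_conformers <- function(residue) {
  at <- residue$atoms
  if (nrow(at) == 0) stop("residue has no atoms")
  inds <- sort(unique(at$altloc[at$altloc != ""]))
  if (length(inds) == 0) {
    st <- list(state_id = "", atoms = at, occupancy = 1.0)
    class(st) <- "ConformerState"
    return(list(st))
  }
  blank <- at[at$altloc == "", , drop = FALSE]
  lapply(inds, function(ind) {
    own <- at[at$altloc == ind, , drop = FALSE]
    atoms <- rbind(blank, own)
    occ_pool <- own$occupancy[own$is_sidechain & !own$is_hydrogen]
    if (length(occ_pool) == 0) occ_pool <- own$occupancy
    uo <- unique(round(occ_pool, 3))
    if (length(uo) > 1) {
      message(sprintf("residue %s %s%s state %s: occupancies disagree (%s); using mode",
                      residue$res_name, residue$chain_id, residue$seq_id, ind,
                      paste(uo, collapse = ",")))
      occ <- as.numeric(names(sort(table(occ_pool), decreasing = TRUE))[1])
    } else {
      occ <- occ_pool[1]
    }
    st <- list(state_id = ind, atoms = atoms, occupancy = occ)
    class(st) <- "ConformerState"
    st
  })
}

#' First conformer of a residue
#'
#' Returns the conformer state with the lexicographically smallest altloc
#' indicator ('A' when present; blank counts as smallest only when it is the
#' sole state). Residues whose indicators start beyond 'A' — e.g. states
#' 'C'/'D' only — are never dropped.
#'
#' @inheritParams group_conformers
#' @return A \code{ConformerState}.
#' @export
first_conformer <- function(residue) {
  group_conformers(residue)[[1]]
}

#' Average side-chain B factor
#'
#' Arithmetic mean of the B factors of heavy atoms other than N, CA, C and
#' O. Undefined (NA) for residues without qualifying atoms (Gly).
#'
#' @inheritParams group_conformers
#' @return Numeric (A^2) or \code{NA_real_} when undefined.
#' @export
sidechain_b_average <- function(residue) {
  at <- residue$atoms
  sel <- at$is_sidechain & !at$is_hydrogen
  if (!any(sel)) return(NA_real_)
  mean(at$b_factor[sel])
}

#' One-letter sequence of a chain
#'
#' Order follows residue sequence ids; altloc multiplicity never duplicates
#' letters; non-amino-acid residues (waters, ligands) are skipped and
#' nonstandard amino acids map to 'X'.
#'
#' @param chain a list of residues (one element of \code{model$chains}).
#' @return A single string.
#' @export
chain_sequence <- function(chain) {
  letters <- vapply(chain, function(res) {
    if (!res$is_aa) return(NA_character_)
    l <- AA3TO1[res$res_name]
    if (is.na(l)) "X" else unname(l)
  }, character(1))
  paste(letters[!is.na(letters)], collapse = "")
}

#' Protein residues of a chain
#' @param chain a list of residues.
#' @return The amino-acid residues only.
#' @export
protein_residues <- function(chain) Filter(residue_is_protein, chain)

#' Coordinates of a named atom within an atom table
#' @keywords internal
atom_xyz <- function(atoms, name) {
  i <- which(atoms$name == name)
  if (length(i) == 0) return(NULL)
  as.numeric(atoms[i[1], c("x", "y", "z")])
}
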