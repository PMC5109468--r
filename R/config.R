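#' Analysis configuration
#'
#' Central container for every tunable cutoff used by the survey and
#' assessment functions. Defaults reproduce the published analysis
#' conditions: a side-chain conformation is "changed" when any chi dihedral
#' differs by strictly more than 30 degrees (after the 180-degree flip for
#' chemically symmetric terminal groups), an atom is density-reliable when
#' its interpolated 2Fo-Fc value is strictly above 1 sigma, a residue is
#' exposed when its absolute accessible surface area is at least 1.0 A^2,
#' and chain pairs are curated at >90\% identity, TM-score >0.8,
#' Ca RMSD <3.0 A, resolution better than 3.5 A and length >100 aa.
#'
#' @param ... named overrides for any default field.
#'
#' @return A list of class \code{scvar_config}.
#' @examples
#' cfg <- scvar_config(chi_change_cutoff_deg = 40)
#' cfg$chi_change_cutoff_deg
#' @export
scvar_config <- function(...) {
  cfg <- list(
    chi_change_cutoff_deg = 30,
    backbone_change_cutoff_deg = 30,
    density_sigma_cutoff = 1.0,
    exposure_asa_cutoff_A2 = 1.0,
    tm_cutoff = 0.8,
    rmsd_cutoff_A = 3.0,
    pair_identity_min_pct = 90,
    nonredundancy_identity_max_pct = 25,
    resolution_max_A = 3.5,
    min_length_aa = 100,
    symmetric_residues = c("ARG", "GLU", "ASP", "PHE", "TYR"),
    # whether Arg's terminal measured chi gets the 180-degree flip; the
    # guanidinium 2-fold does not strictly act on chi4 but the published
    # comparison flips all five listed residue types
    flip_arg_terminal = TRUE,
    # reliability evaluated on the first conformer only (any-conformer
    # evaluation available for sensitivity checks)
    reliability_first_conformer_only = TRUE,
    # SASA
    probe_radius_A = 1.4,
    sasa_n_points = 960,
    include_het_in_occlusion = FALSE,
    # alignment
    gap_open = 10,
    gap_extend = 0.5,
    # aggregation: population SD across per-structure percentages
    sd_type = c("population", "sample"),
    # density interpolation: trilinear is the contract
    interpolation = "trilinear",
    # assessment
    closest_metric = c("minimax", "chi1_lex")
  )
  cfg$sd_type <- cfg$sd_type[1]
  cfg$closest_metric <- cfg$closest_metric[1]
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  num <- c("chi_change_cutoff_deg", "backbone_change_cutoff_deg",
           "density_sigma_cutoff", "exposure_asa_cutoff_A2", "tm_cutoff",
           "rmsd_cutoff_A", "resolution_max_A", "probe_radius_A")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("config field ", f, " must be a positive number")
  }
  class(cfg) <- "scvar_config"
  cfg
}

#' Read a flat key=value configuration file
#'
#' Lines are \code{key = value}; blank lines and lines starting with
#' \code{#} are ignored. Values that parse as numbers become numeric;
#' comma-separated values become character vectors.
#'
#' @param path path to the config file.
#' @return A \code{scvar_config}.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  overrides <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (grepl(",", val, fixed = TRUE)) {
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) val <- num
      else if (val %in% c("TRUE", "FALSE", "true", "false"))
        val <- as.logical(toupper(val))
    }
    overrides[[key]] <- val
  }
  do.call(scvar_config, overrides)
}

# ---- residue chemistry tables -------------------------------------------

# three-letter -> one-letter code for the 20 standard amino acids
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# common HETATM amino-acid variants mapped to standard parents
HET_PARENT <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", HSD = "HIS",
                HSE = "HIS", HSP = "HIS", CSO = "CYS", SEP = "SER",
                TPO = "THR", PTR = "TYR", MLY = "LYS")

#' Standard chi dihedral atom quadruples
#'
#' For each standard residue type, the ordered list of chi angles, each
#' defined by four atom names (IUPAC convention; chi1 is N-CA-CB-Xgamma).
#' Pro's chi2 is measured and reported but the residue counts as a single
#' degree of freedom in type summaries.
#'
#' @return Named list: residue type -> list of character(4) atom quadruples.
#' @export
chi_atom_table <- function() CHI_TABLE

CHI_TABLE <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  ALA = list(),
  GLY = list()
)

# index of the terminal chi whose defining group is chemically 2-fold
# symmetric (180-degree flip equivalence in comparisons); Arg handled via
# config$flip_arg_terminal
SYMMETRIC_TERMINAL_CHI <- c(ASP = 2L, GLU = 3L, PHE = 2L, TYR = 2L, ARG = 4L)

# element-based van der Waals radii (A), NACCESS-compatible scale
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               H = 1.20, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
               I = 1.98)
VDW_DEFAULT <- 1.70

# Gly-X-Gly reference ASA (A^2) for relative ASA (Miller tripeptide scale;
# matches what an extended tripeptide yields under these vdW radii)
REF_ASA <- c(
  ALA = 113, ARG = 241, ASN = 158, ASP = 151, CYS = 140,
  GLN = 189, GLU = 183, GLY = 85, HIS = 194, ILE = 182,
  LEU = 180, LYS = 211, MET = 204, PHE = 218, PRO = 143,
  SER = 122, THR = 146, TRP = 259, TYR = 229, VAL = 160
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
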