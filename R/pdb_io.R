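#' Read a PDB-format coordinate file
#'
#' Parses fixed-column (v3.3 dialect) ATOM/HETATM records preserving
#' alternate-location indicators, occupancies and B factors. Hydrogens are
#' retained but flagged. The resolution is taken from the
#' \code{REMARK   2 RESOLUTION} header when present. HETATM amino-acid
#' variants (e.g. MSE) are mapped to their standard parents and flagged;
#' waters and ligands are kept as non-amino-acid residues and excluded from
#' all residue statistics downstream. Multi-MODEL files: only the first
#' MODEL is read, with a warning.
#'
#' @param source path to a PDB file, or a character vector of PDB lines
#'   (anything containing a newline or of length > 1 is treated as text).
#' @return A \code{StructureModel}.
#' @examples
#' m <- make_synthetic_chain(3, c("SER", "ASP", "LEU"), seed = 1)$model
#' txt <- write_pdb(m)
#' m2 <- read_pdb(txt)
#' @export
read_pdb <- function(source) {
  if (length(source) > 1 || grepl("\n", source[1], fixed = TRUE)) {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
  } else {
    if (!file.exists(source)) stop("no such file: ", source)
    lines <- readLines(source, warn = FALSE)
  }
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop("empty PDB input")

  pdb_id <- "xxxx"
  resolution <- NA_real_
  hdr <- grep("^HEADER", lines, value = TRUE)
  if (length(hdr)) {
    id <- trimws(substr(hdr[1], 63, 66))
    if (nzchar(id)) pdb_id <- tolower(id)
  }
  rem <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem)) {
    tail_ <- substr(rem[1], 23, 80)
    m <- regmatches(tail_, regexpr("[0-9]+\\.?[0-9]*", tail_))
    if (length(m)) resolution <- as.numeric(m)
  }

  # first MODEL only
  model_starts <- grep("^MODEL ", lines)
  if (length(model_starts) > 1) {
    warning("multi-MODEL file: using first MODEL only")
    endm <- grep("^ENDMDL", lines)
    lines <- lines[seq_len(if (length(endm)) endm[1] else length(lines))]
  }

  sel <- grep("^(ATOM  |HETATM)", lines)
  if (length(sel) == 0) stop("no ATOM/HETATM records found")
  recs <- lines[sel]
  fw <- function(a, b) substr(recs, a, b)
  x <- suppressWarnings(as.numeric(fw(31, 38)))
  y <- suppressWarnings(as.numeric(fw(39, 46)))
  z <- suppressWarnings(as.numeric(fw(47, 54)))
  occ <- suppressWarnings(as.numeric(fw(55, 60)))
  bfac <- suppressWarnings(as.numeric(fw(61, 66)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed coordinate fields at line ", sel[bad[1]], ": ",
         recs[bad[1]])
  occ[is.na(occ)] <- 1.0
  bfac[is.na(bfac)] <- 0.0
  if (any(occ < -1e-9 | occ > 1 + 1e-6))
    message("occupancy outside [0,1] observed; kept as parsed")

  name <- trimws(fw(13, 16))
  altloc <- fw(17, 17)
  altloc[altloc == " "] <- ""
  res_name <- trimws(fw(18, 20))
  chain <- fw(22, 22)
  resnum <- suppressWarnings(as.integer(fw(23, 26)))
  if (anyNA(resnum))
    stop("malformed residue number at line ", sel[which(is.na(resnum))[1]])
  icode <- trimws(fw(27, 27))
  element <- toupper(trimws(fw(77, 78)))
  # infer element from atom name where the element column is blank
  miss <- !nzchar(element)
  if (any(miss)) {
    nm <- gsub("[0-9']", "", name[miss])
    element[miss] <- ifelse(startsWith(nm, "H"), "H",
                            substr(nm, 1, 1))
  }
  is_het <- startsWith(recs, "HETATM")

  atoms <- new_atom_table(name, element, x, y, z, altloc, occ, bfac, is_het)
  key <- paste(chain, resnum, icode, res_name, sep = "\r")
  chains <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    parts <- c(parts, rep("", 4 - length(parts)))
    res <- new_residue(parts[4], as.integer(parts[2]), parts[3], parts[1],
                       atoms[idx, , drop = FALSE],
                       is_het = all(is_het[idx]))
    cid <- parts[1]
    chains[[cid]] <- c(chains[[cid]], list(res))
  }
  # order residues within each chain by (number, icode)
  chains <- lapply(chains, function(ch) {
    ord <- order(vapply(ch, `[[`, integer(1), "number"),
                 vapply(ch, `[[`, character(1), "icode"))
    ch[ord]
  })
  check_occupancy_sums(chains)
  new_structure_model(pdb_id, resolution, chains)
}

# per atom name, occupancies across altloc states should sum to <= 1;
# violations are logged, never fatal
check_occupancy_sums <- function(chains) {
  for (ch in chains) for (res in ch) {
    at <- res$atoms
    alt <- at[at$altloc != "" & at$is_sidechain & !at$is_hydrogen, ,
              drop = FALSE]
    if (nrow(alt) == 0) next
    sums <- tapply(alt$occupancy, alt$name, sum)
    if (any(sums > 1 + 1e-6))
      message(sprintf("residue %s %s%s: altloc occupancies sum to %.3f > 1",
                      res$res_name, res$chain_id, res$seq_id, max(sums)))
  }
  invisible(NULL)
}

#' Write a StructureModel as PDB text
#'
#' Emits fixed-column ATOM/HETATM records (altloc, occupancy, B factor
#' included) re-readable by \code{\link{read_pdb}}. Coordinates must fit
#' the 8.3 field.
#'
#' @param model a \code{StructureModel}.
#' @param path optional file path; when given the text is also written there.
#' @return The PDB text as a single string (invisibly when \code{path} given).
#' @export
write_pdb <- function(model, path = NULL) {
  out <- character(0)
  out <- c(out, sprintf("%-62s%4s", "HEADER    SYNTHETIC STRUCTURE",
                        toupper(model$pdb_id)))
  if (!is.na(model$resolution))
    out <- c(out, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                          model$resolution))
  serial <- 0L
  for (cid in names(model$chains)) {
    ch <- model$chains[[cid]]
    for (res in ch) {
      at <- res$atoms
      for (i in seq_len(nrow(at))) {
        serial <- serial + 1L
        if (any(abs(c(at$x[i], at$y[i], at$z[i])) >= 10000))
          stop("coordinate exceeds PDB field width")
        nm <- at$name[i]
        # column-13 alignment: 1-3 char names start in column 14
        nm_f <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
        rec <- if (at$is_het[i]) "HETATM" else "ATOM  "
        out <- c(out, sprintf(
          "%s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial %% 100000L, nm_f,
          ifelse(at$altloc[i] == "", " ", at$altloc[i]),
          res$orig_name, cid, res$number,
          ifelse(res$icode == "", " ", res$icode),
          at$x[i], at$y[i], at$z[i], at$occupancy[i], at$b_factor[i],
          at$element[i]))
      }
    }
    out <- c(out, "TER")
  }
  out <- c(out, "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(txt))
  }
  txt
}
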