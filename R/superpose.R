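#' Kabsch least-squares superposition
#'
#' Optimal proper rotation (reflection-corrected) and translation mapping
#' \code{P} onto \code{Q}, with the post-superposition RMSD.
#'
#' @param P,Q n x 3 matrices of matched coordinates (A), n >= 3.
#' @return List of class \code{SuperpositionResult}: \code{rotation} (3x3,
#'   det +1), \code{translation}, \code{rmsd}. The transform maps a point p
#'   as \code{rotation \%*\% p + translation}.
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3)
    stop("P and Q must be matched n x 3 matrices")
  if (nrow(P) < 3) stop("need at least 3 points for superposition")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tvec <- cq - as.numeric(R %*% cp)
  Pfit <- t(R %*% t(P)) + matrix(tvec, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((Pfit - Q)^2)))
  structure(list(rotation = R, translation = tvec, rmsd = rmsd),
            class = "SuperpositionResult")
}

apply_transform <- function(P, R, tvec) {
  t(R %*% t(P)) + matrix(tvec, nrow(P), 3, byrow = TRUE)
}

tm_d0 <- function(l_target) {
  d0 <- 1.24 * (max(l_target, 16) - 15)^(1 / 3) - 1.8
  max(d0, 0.5)
}

ca_matrix <- function(chain) {
  res <- protein_residues(chain)
  xs <- lapply(res, function(r) atom_xyz(first_conformer(r)$atoms, "CA"))
  keep <- !vapply(xs, is.null, logical(1))
  m <- do.call(rbind, xs[keep])
  attr(m, "index") <- which(keep)
  m
}

#' TM-score of a paired chain superposition
#'
#' \code{TM = (1/L_target) * sum 1/(1 + (d_i/d0)^2)} with
#' \code{d0 = 1.24 (L_target - 15)^(1/3) - 1.8} (floored at 0.5 A for short
#' targets). The superposition starts from an all-pair Kabsch fit and is
#' iteratively refined on the residues with \code{d_i < max(d0, 3)} until
#' the included set repeats (max 20 iterations); ties break toward the
#' larger included set by accepting the first repeat. Normalization is by
#' the reference (first) chain length.
#'
#' @param chainA,chainB residue lists, or directly n x 3 Ca coordinate
#'   matrices (already matched when matrices).
#' @param pairing optional data.frame with columns \code{i}, \code{j}
#'   (1-based indices into the protein residues of each chain); default
#'   pairs by index over the common length.
#' @param l_target normalization length; default the reference chain length.
#' @return A \code{SuperpositionResult} with \code{tm_score} and \code{d0}.
#' @export
tm_score <- function(chainA, chainB, pairing = NULL, l_target = NULL) {
  if (is.matrix(chainA)) {
    P <- chainA; Q <- chainB
    if (is.null(l_target)) l_target <- nrow(P)
  } else {
    P_all <- ca_matrix(chainA); Q_all <- ca_matrix(chainB)
    if (is.null(l_target)) l_target <- length(protein_residues(chainA))
    if (is.null(pairing)) {
      n <- min(nrow(P_all), nrow(Q_all))
      pairing <- data.frame(i = seq_len(n), j = seq_len(n))
    }
    ia <- match(pairing$i, attr(P_all, "index"))
    ib <- match(pairing$j, attr(Q_all, "index"))
    keep <- !is.na(ia) & !is.na(ib)
    P <- P_all[ia[keep], , drop = FALSE]
    Q <- Q_all[ib[keep], , drop = FALSE]
  }
  if (nrow(P) < 3) stop("pairing shorter than 3")
  d0 <- tm_d0(l_target)
  cut <- max(d0, 3)

  fit <- kabsch_superpose(P, Q)
  included <- seq_len(nrow(P))
  seen <- list(sort(included))
  for (it in seq_len(20)) {
    Pfit <- apply_transform(P, fit$rotation, fit$translation)
    d <- sqrt(rowSums((Pfit - Q)^2))
    new_inc <- which(d < cut)
    if (length(new_inc) < 3) new_inc <- order(d)[seq_len(3)]
    key <- sort(new_inc)
    if (any(vapply(seen, identical, logical(1), y = key))) break
    seen <- c(seen, list(key))
    included <- new_inc
    fit <- kabsch_superpose(P[included, , drop = FALSE],
                            Q[included, , drop = FALSE])
  }
  Pfit <- apply_transform(P, fit$rotation, fit$translation)
  d <- sqrt(rowSums((Pfit - Q)^2))
  tm <- sum(1 / (1 + (d / d0)^2)) / l_target
  rmsd_all <- kabsch_superpose(P, Q)$rmsd
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = rmsd_all, tm_score = tm, d0 = d0),
            class = "SuperpositionResult")
}
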