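# Structure-similarity machinery: Kabsch superposition, the TM-score d0
# normalization, local TM-score conservation weights for reference
# alignments, TM-score and GDT with a fragment-seeded superposition search,
# and aligned-pair precision/recall.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing
#' sum_i || X_i - (R Y_i + t) ||^2.
#'
#' @param X,Y n x 3 coordinate matrices (n >= 3, non-degenerate).
#' @return A `superposition`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3) and `rmsd`. Apply with
#'   `sweep(Y %*% t(R), 2, t, "+")` via [apply_superposition()].
#' @export
kabsch_superpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3 || nrow(Y) != n) stop_format("kabsch requires n >= 3 matched points")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  C <- crossprod(Yc, Xc)  # 3x3 covariance
  if (qr(C)$rank < 2) stop_format("degenerate point set: rank-deficient covariance")
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  # Y maps as y -> R %*% y; translation aligns centroids
  Yr <- Yc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Xc - Yr)^2)))
  tr <- cx - as.vector(R %*% cy)
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "superposition")
}

#' @rdname kabsch_superpose
#' @param sp a `superposition`.
#' @export
apply_superposition <- function(sp, Y) {
  sweep(as.matrix(Y) %*% t(sp$rotation), 2, sp$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' TM-score length normalization constant
#'
#' `d0(L) = 1.24 (L - 15)^(1/3) - 1.8`, floored at 0.5 Angstrom (the
#' standard TM-score convention; short proteins fall entirely on the floor).
#'
#' @param L protein length (>= 1); vectorized.
#' @return d0 in Angstrom.
#' @export
d0 <- function(L) {
  stopifnot(all(L >= 1))
  raw <- 1.24 * (pmax(L - 15, 0))^(1 / 3) - 1.8
  pmax(raw, 0.5)
}

#' Local TM-score weights for a reference alignment
#'
#' Superposes the aligned C-alpha sets, then weights every aligned pair by
#' `w = 1 / (1 + (d/d0)^2)` where d is the post-superposition distance and
#' d0 is evaluated at the mean of the two protein lengths. Gapped positions
#' carry weight 0 by convention (they simply have no pair).
#'
#' @param ref [reference_alignment] (weights ignored on input).
#' @param caT,caQ template and query C-alpha coordinate matrices.
#' @return The reference alignment with weights filled in.
#' @export
local_tm_weights <- function(ref, caT, caQ) {
  pr <- ref$pairs
  if (nrow(pr) < 3) stop_format("need >= 3 aligned pairs to superpose")
  if (max(pr[, 1]) > nrow(caT) || max(pr[, 2]) > nrow(caQ))
    stop_format("alignment indices exceed coordinate ranges")
  sp <- kabsch_superpose(caT[pr[, 1], , drop = FALSE],
                         caQ[pr[, 2], , drop = FALSE])
  qs <- apply_superposition(sp, caQ[pr[, 2], , drop = FALSE])
  d <- sqrt(rowSums((caT[pr[, 1], , drop = FALSE] - qs)^2))
  dd0 <- d0(round((nrow(caT) + nrow(caQ)) / 2))
  reference_alignment(pr, 1 / (1 + (d / dd0)^2))
}

# Shared fragment-seeded superposition search used by tm_score and gdt.
# For each seed fragment the model is superposed on the fragment, then the
# subset of pairs within `cutoff` is iteratively re-superposed until the
# subset is stable. Returns the list of candidate superpositions.
seeded_superpositions <- function(Xr, Xm, cutoff, max_iter = 20L) {
  n <- nrow(Xr)
  frags <- unique(pmax(3L, c(4L, floor(n / 4), floor(n / 2), n)))
  sps <- list(kabsch_superpose(Xr, Xm))
  for (Lf in frags) {
    if (Lf > n) next
    starts <- unique(c(seq(1L, n - Lf + 1L, by = max(1L, Lf %/% 2L)),
                       n - Lf + 1L))
    for (s in starts) {
      idx <- s:(s + Lf - 1L)
      sp <- tryCatch(kabsch_superpose(Xr[idx, , drop = FALSE],
                                      Xm[idx, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(sp)) next
      prev <- integer(0)
      for (it in seq_len(max_iter)) {
        d <- sqrt(rowSums((Xr - apply_superposition(sp, Xm))^2))
        co <- cutoff
        sel <- which(d < co)
        while (length(sel) < 3 && co < 1e3) { co <- co + 1; sel <- which(d < co) }
        if (identical(sel, prev)) break
        prev <- sel
        sp2 <- tryCatch(kabsch_superpose(Xr[sel, , drop = FALSE],
                                         Xm[sel, , drop = FALSE]),
                        error = function(e) NULL)
        if (is.null(sp2)) break
        sp <- sp2
      }
      sps[[length(sps) + 1L]] <- sp
    }
  }
  sps
}

#' TM-score of a model against a reference
#'
#' `(1/L_norm) * sum_i 1 / (1 + (d_i/d0(L_norm))^2)` maximized over
#' superpositions found by a fragment-seeded iterative-extension search
#' (seeds of length 4, L/4, L/2 and L; pairs within a distance cutoff are
#' re-superposed until a fixed point). A bounded search, so a (tight) lower
#' bound on the exhaustive optimum; it is never below the single
#' all-pair Kabsch superposition.
#'
#' @param pairs n x 2 index matrix mapping reference residues (col 1) to
#'   model residues (col 2); use `cbind(1:L, 1:L)` for self-comparison.
#' @param caRef,caModel coordinate matrices.
#' @param L_norm normalization length.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(pairs, caRef, caModel, L_norm) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) < 3) stop_format("tm_score needs >= 3 aligned pairs")
  Xr <- caRef[pairs[, 1], , drop = FALSE]
  Xm <- caModel[pairs[, 2], , drop = FALSE]
  dd0 <- d0(L_norm)
  best <- 0
  for (sp in seeded_superpositions(Xr, Xm, cutoff = max(dd0, 4.0))) {
    d <- sqrt(rowSums((Xr - apply_superposition(sp, Xm))^2))
    best <- max(best, sum(1 / (1 + (d / dd0)^2)) / L_norm)
  }
  best
}

#' GDT (Global Distance Test), normalized to [0, 1]
#'
#' Mean over distance cutoffs {1, 2, 4, 8} Angstrom of the maximal fraction
#' of residues (of `L_norm`) superposable within the cutoff, using the same
#' fragment-seeded search as [tm_score()] per cutoff.
#'
#' @inheritParams tm_score
#' @return GDT score in [0, 1].
#' @export
gdt <- function(pairs, caRef, caModel, L_norm) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) < 3) stop_format("gdt needs >= 3 aligned pairs")
  Xr <- caRef[pairs[, 1], , drop = FALSE]
  Xm <- caModel[pairs[, 2], , drop = FALSE]
  fracs <- vapply(c(1, 2, 4, 8), function(cutoff) {
    best <- 0
    for (sp in seeded_superpositions(Xr, Xm, cutoff = cutoff)) {
      d <- sqrt(rowSums((Xr - apply_superposition(sp, Xm))^2))
      best <- max(best, sum(d < cutoff) / L_norm)
    }
    best
  }, numeric(1))
  mean(pmin(fracs, 1))
}

#' Precision / recall / F1 of predicted aligned pairs
#'
#' A predicted pair counts as correct only if the exact (template, query)
#' index pair occurs in the reference. With an empty prediction, precision
#' is 0 unless the reference is also empty (then 1); symmetrically for
#' recall.
#'
#' @param pred alignment with `$pairs` (e.g. from [mac_align()]).
#' @param ref [reference_alignment] (or anything with `$pairs`).
#' @return List with `precision`, `recall`, `f1`.
#' @export
pair_accuracy <- function(pred, ref) {
  key <- function(p) if (nrow(p) == 0) character(0)
                     else paste(p[, 1], p[, 2], sep = ":")
  kp <- key(pred$pairs); kr <- key(ref$pairs)
  hits <- length(intersect(kp, kr))
  precision <- if (length(kp) == 0) as.numeric(length(kr) == 0)
               else hits / length(kp)
  recall <- if (length(kr) == 0) as.numeric(length(kp) == 0)
            else hits / length(kr)
  f1 <- if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}
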