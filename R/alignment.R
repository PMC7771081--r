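# Maximum Accuracy (MAC) alignment: a local dynamic program over the
# residue-residue aligning probability matrix. Matching cell (i, j) earns
# p_ij - alpha; every gap step inside the local path costs alpha / 2;
# the path may start and end anywhere (terminal gaps are free). alpha
# controls greediness: larger alpha yields shorter, more confident
# alignments.

#' Optimal sub-alignment score matrix
#'
#' Computes the (L_T + 1) x (L_Q + 1) matrix `S` with zero boundary and
#' `S[i, j] = max(S[i-1, j-1] + p_ij - alpha, S[i-1, j] - alpha/2,
#' S[i, j-1] - alpha/2, 0)`. The diagonal accumulation term implements the
#' Maximum Accuracy recursion of the posterior-decoding alignment
#' literature; `recursion = "printed"` drops the `S[i-1, j-1]` accumulation
#' (making the match branch `p_ij - alpha` alone) for comparison.
#'
#' @param p L_T x L_Q matrix of aligning probabilities.
#' @param alpha greediness penalty (>= 0).
#' @param mask optional logical matrix; masked-out cells cannot be matched.
#' @param recursion `"accumulating"` (default) or `"printed"`.
#' @return List with `S` (score matrix, including the zero boundary row and
#'   column) and `choice` (trace codes: 0 stop, 1 diagonal, 2 up, 3 left).
#' @export
mac_matrix <- function(p, alpha, mask = NULL,
                       recursion = c("accumulating", "printed")) {
  recursion <- match.arg(recursion)
  if (alpha < 0) stop_format("alpha must be >= 0")
  p <- as.matrix(p)
  LT <- nrow(p); LQ <- ncol(p)
  if (!is.null(mask)) p[!mask] <- -Inf
  S <- matrix(0, LT + 1, LQ + 1)
  choice <- matrix(0L, LT + 1, LQ + 1)
  g <- alpha / 2
  for (i in seq_len(LT)) {
    Sprev <- S[i, ]
    Srow <- S[i + 1, ]
    chrow <- choice[i + 1, ]
    for (j in seq_len(LQ)) {
      diag_base <- if (recursion == "accumulating") Sprev[j] else 0
      v_diag <- diag_base + p[i, j] - alpha
      v_up <- Sprev[j + 1] - g
      v_left <- Srow[j] - g
      # tie-break priority: diagonal > up > left > stop
      best <- v_diag; ch <- 1L
      if (v_up > best) { best <- v_up; ch <- 2L }
      if (v_left > best) { best <- v_left; ch <- 3L }
      if (0 >= best) { best <- 0; ch <- 0L }
      Srow[j + 1] <- best
      chrow[j + 1] <- ch
    }
    S[i + 1, ] <- Srow
    choice[i + 1, ] <- chrow
  }
  list(S = S, choice = choice, alpha = alpha, recursion = recursion)
}

#' Traceback of the MAC score matrix
#'
#' Starts at the global argmax of `S` (ties: smallest i, then j) and follows
#' the recorded choices until a stop cell, emitting matched (diagonal) cells.
#'
#' @param mac result of [mac_matrix()].
#' @return An `alignment_result`: list with monotone `pairs` (t, q), the
#'   optimal `score` (>= 0; 0 iff no pairs) and `alpha`.
#' @export
mac_traceback <- function(mac) {
  S <- mac$S; choice <- mac$choice
  best <- max(S)
  hit <- which(S == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
  i <- hit[1]; j <- hit[2]
  tpairs <- integer(0); qpairs <- integer(0)
  while (i > 1 || j > 1) {
    ch <- choice[i, j]
    if (ch == 0L) break
    if (ch == 1L) {
      tpairs <- c(i - 1L, tpairs); qpairs <- c(j - 1L, qpairs)
      i <- i - 1L; j <- j - 1L
    } else if (ch == 2L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  score <- if (length(tpairs) == 0) 0 else best
  structure(
    list(pairs = cbind(t = tpairs, q = qpairs), score = score,
         alpha = mac$alpha),
    class = "alignment_result"
  )
}

#' Maximum Accuracy alignment of a probability matrix
#'
#' Composition of [mac_matrix()] and [mac_traceback()]. The optimal score is
#' the key used to rank templates during threading.
#'
#' @inheritParams mac_matrix
#' @return An `alignment_result` (see [mac_traceback()]).
#' @export
mac_align <- function(p, alpha = 0.3, mask = NULL,
                      recursion = c("accumulating", "printed")) {
  mac_traceback(mac_matrix(p, alpha, mask, recursion))
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d pairs, MAC score %.6f (alpha = %g)\n",
              nrow(x$pairs), x$score, x$alpha))
  invisible(x)
}

#' Exhaustive Maximum Accuracy oracle
#'
#' Enumerates every monotone set of matched cells (every local alignment),
#' scoring `sum(p - alpha)` over matches minus `alpha/2` per interior gap
#' step between consecutive matches, and returns the maximum. Exponential;
#' guarded to small matrices. Used as an independent test oracle for
#' [mac_align()].
#'
#' @inheritParams mac_matrix
#' @param max_cells guard on `L_T * L_Q` (default 30).
#' @return An `alignment_result` with an extra `n_optima` count of distinct
#'   optimal match sets (within 1e-12).
#' @export
brute_force_align <- function(p, alpha, max_cells = 30L) {
  p <- as.matrix(p)
  LT <- nrow(p); LQ <- ncol(p)
  if (LT * LQ > max_cells)
    stop_format("brute_force_align limited to %d cells (got %d)",
                max_cells, LT * LQ)
  best <- list(score = 0, pairs = cbind(t = integer(0), q = integer(0)),
               n_optima = 1L)  # the empty alignment scores 0
  tol <- 1e-12
  consider <- function(score, tp, qp) {
    if (score > best$score + tol) {
      best$score <<- score
      best$pairs <<- cbind(t = tp, q = qp)
      best$n_optima <<- 1L
    } else if (abs(score - best$score) <= tol) {
      best$n_optima <<- best$n_optima + 1L
    }
  }
  recurse <- function(last_i, last_j, score, tp, qp) {
    if (last_i >= LT || last_j >= LQ) return(invisible(NULL))
    for (i in (last_i + 1L):LT) {
      for (j in (last_j + 1L):LQ) {
        gap <- if (length(tp) == 0) 0
               else (alpha / 2) * ((i - last_i - 1L) + (j - last_j - 1L))
        sc <- score + p[i, j] - alpha - gap
        consider(sc, c(tp, i), c(qp, j))
        recurse(i, j, sc, c(tp, i), c(qp, j))
      }
    }
  }
  recurse(0L, 0L, 0, integer(0), integer(0))
  structure(
    list(pairs = best$pairs, score = best$score, alpha = alpha,
         n_optima = best$n_optima),
    class = "alignment_result"
  )
}
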