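# Pairwise feature construction: sequence profiles, observed and predicted
# sequential structural features, contact maps and their eigenvector
# embeddings, assembled into the L_T x L_Q x 77 pair tensor scored by the
# network.
#
# Channel layout (fixed; serialized models depend on it):
#   [ 1:20]  template profile        [21:40]  query profile
#   [41:53]  template observed structural features (13)
#   [54:61]  template predicted features (8)
#   [62:69]  query predicted features (8)
#   [70:77]  contact eigen-pair features (8)
N_CHANNELS <- 77L

#' Positional amino-acid profile from an MSA
#'
#' Column-wise amino-acid frequencies over non-gap, non-`X` symbols with an
#' additive pseudocount, renormalized so every row lies on the simplex.
#' Columns with no informative symbol become uniform.
#'
#' @param msa a [protein_msa].
#' @param pseudocount additive pseudocount per amino acid (default `1e-3`).
#' @return L x 20 matrix of per-position amino-acid frequencies, columns in
#'   the fixed `AA_ALPHABET` order.
#' @export
profile_from_msa <- function(msa, pseudocount = 1e-3) {
  rows <- do.call(rbind, strsplit(msa$rows, ""))
  L <- ncol(rows)
  prof <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(L)) {
    col <- rows[, j]
    col <- col[col %in% AA_ALPHABET]
    cnt <- if (length(col) > 0) table(factor(col, levels = AA_ALPHABET))
           else rep(0, 20)
    f <- as.numeric(cnt) + pseudocount
    tot <- sum(f)
    prof[j, ] <- if (tot > 0) f / tot else rep(1 / 20, 20)
  }
  prof
}

#' Contact numbers from coordinates
#'
#' Counts, for every residue, the non-neighbouring residues (|i - j| >= 2)
#' within 8 Angstrom, once with C-alpha - C-alpha and once with
#' C-beta - C-beta distances, scaled by 0.1 to keep the channels O(1).
#'
#' @param record [protein_record] with both coordinate sets.
#' @param threshold distance threshold in Angstrom (default 8).
#' @return L x 2 matrix (C-alpha counts, C-beta counts) x 0.1.
#' @export
contact_numbers <- function(record, threshold = 8.0) {
  if (is.null(record$ca_coords) || is.null(record$cb_coords))
    stop_format("contact_numbers requires both ca_coords and cb_coords")
  count_for <- function(xyz) {
    L <- nrow(xyz)
    d <- as.matrix(stats::dist(xyz))
    near <- d < threshold
    idx <- abs(outer(seq_len(L), seq_len(L), "-")) >= 2
    unname(rowSums(near & idx))
  }
  0.1 * cbind(count_for(record$ca_coords), count_for(record$cb_coords))
}

#' Observed (DSSP-like) template features
#'
#' Per residue: 8-state secondary-structure one-hot (8), relative solvent
#' accessibility (1), phi/180 and psi/180 (2, missing angles encoded 0),
#' and the two contact-number channels from [contact_numbers()]. 13 columns.
#'
#' @param record template [protein_record] with coordinates.
#' @param ann [annotation_table] with `ss8`, `rsa`, `phi`, `psi`.
#' @return L x 13 feature matrix.
#' @export
observed_template_features <- function(record, ann) {
  L <- length(record)
  if (nrow(ann) != L)
    stop_format("annotation rows (%d) do not match protein length (%d)",
                nrow(ann), L)
  for (col in c("ss8", "rsa", "phi", "psi"))
    if (is.null(ann[[col]]))
      stop_format("observed annotation is missing column '%s'", col)
  onehot <- matrix(0, L, 8)
  onehot[cbind(seq_len(L), match(ann$ss8, SS8_STATES))] <- 1
  ang <- function(v) unname(ifelse(is.na(v), 0, v / 180))
  out <- cbind(onehot, unname(ann$rsa), ang(ann$phi), ang(ann$psi),
               contact_numbers(record))
  dimnames(out) <- NULL
  out
}

#' Predicted sequential structural features
#'
#' Per residue: 3-state secondary-structure one-hot (3), predicted solvent
#' accessibility (1), phi/180 and psi/180 (2), interface probability (1)
#' and disorder probability (1). 8 columns, used for both template and query.
#'
#' @param ann [annotation_table] with `ss3`, `rsa`, `phi`, `psi`,
#'   `interface_prob`, `disorder_prob`.
#' @return L x 8 feature matrix.
#' @export
predicted_features <- function(ann) {
  for (col in c("ss3", "rsa", "phi", "psi", "interface_prob",
                "disorder_prob"))
    if (is.null(ann[[col]]))
      stop_format("predicted annotation is missing column '%s'", col)
  L <- nrow(ann)
  onehot <- matrix(0, L, 3)
  onehot[cbind(seq_len(L), match(ann$ss3, SS3_STATES))] <- 1
  ang <- function(v) unname(ifelse(is.na(v), 0, v / 180))
  out <- cbind(onehot, unname(ann$rsa), ang(ann$phi), ang(ann$psi),
               unname(ann$interface_prob), unname(ann$disorder_prob))
  dimnames(out) <- NULL
  out
}

#' Binary contact map from C-beta coordinates
#'
#' Entry (i, j) is 1 iff the C-beta - C-beta distance is strictly below the
#' threshold (8 Angstrom by convention); the diagonal is 0.
#'
#' @param record [protein_record] with `cb_coords`.
#' @param threshold contact threshold in Angstrom.
#' @return A `contact_map` object: list with symmetric 0/1 matrix `m` and
#'   `kind = "binary_observed"`.
#' @export
contact_map_from_coords <- function(record, threshold = 8.0) {
  if (is.null(record$cb_coords))
    stop_format("contact_map_from_coords requires cb_coords")
  d <- as.matrix(stats::dist(record$cb_coords))
  m <- (d < threshold) * 1
  diag(m) <- 0
  dimnames(m) <- NULL
  contact_map(m, kind = "binary_observed")
}

#' Contact map container
#'
#' @param m square symmetric matrix; binary for observed maps, values in
#'   [0, 1] for predicted probability maps.
#' @param kind `"binary_observed"` or `"predicted_prob"`.
#' @return A `contact_map` object.
#' @export
contact_map <- function(m, kind = c("binary_observed", "predicted_prob")) {
  kind <- match.arg(kind)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_format("contact map must be square")
  if (max(abs(m - t(m))) > 1e-9) stop_format("contact map must be symmetric")
  if (kind == "binary_observed" && !all(m %in% c(0, 1)))
    stop_format("binary_observed contact map entries must be 0/1")
  structure(list(m = m, kind = kind), class = "contact_map")
}

#' Eigenvector embedding of a contact map
#'
#' Symmetric eigendecomposition; the K eigenpairs of largest magnitude
#' |lambda| are retained, ordered by |lambda| descending with ties broken
#' toward the algebraically larger eigenvalue. Each residue i is then
#' represented as (sqrt(lambda_1) v_1i, ..., sqrt(lambda_K) v_Ki).
#' Proteins shorter than K are padded with zero eigenpairs.
#'
#' @param cm [contact_map] (binary observed or predicted probabilities).
#' @param K number of eigenpairs to keep (default 8).
#' @return An `eigen_embedding`: list with `K`, `lambdas` (length K) and
#'   `vectors` (K x L, unit rows).
#' @export
eigen_embedding <- function(cm, K = 8L) {
  stopifnot(K >= 1)
  m <- if (inherits(cm, "contact_map")) cm$m else as.matrix(cm)
  L <- nrow(m)
  e <- eigen(m, symmetric = TRUE)
  ord <- order(-abs(e$values), -e$values)
  k_eff <- min(K, L)
  sel <- ord[seq_len(k_eff)]
  lambdas <- e$values[sel]
  vectors <- t(e$vectors[, sel, drop = FALSE])
  if (k_eff < K) {
    lambdas <- c(lambdas, rep(0, K - k_eff))
    vectors <- rbind(vectors, matrix(0, K - k_eff, L))
  }
  structure(list(K = as.integer(K), lambdas = lambdas, vectors = vectors),
            class = "eigen_embedding")
}

#' Contact eigen-pair features
#'
#' Channel k at (i, j) is `sqrt(|lambda_k^T * lambda_k^Q|) * |v_ki^T| *
#' |v_kj^Q|`. The absolute values make the feature invariant to eigenvector
#' sign, and the absolute value under the root keeps the radicand
#' non-negative when eigenvalues of mixed sign pair up.
#'
#' @param embT,embQ [eigen_embedding]s with equal `K`.
#' @return L_T x L_Q x K array.
#' @export
eigen_pair_features <- function(embT, embQ) {
  if (embT$K != embQ$K)
    stop_format("eigen embeddings have different K (%d vs %d)",
                embT$K, embQ$K)
  K <- embT$K
  LT <- ncol(embT$vectors); LQ <- ncol(embQ$vectors)
  out <- array(0, dim = c(LT, LQ, K))
  for (k in seq_len(K)) {
    scale_k <- sqrt(abs(embT$lambdas[k] * embQ$lambdas[k]))
    out[, , k] <- scale_k * outer(abs(embT$vectors[k, ]),
                                  abs(embQ$vectors[k, ]))
  }
  out
}

#' Assemble the pairwise feature tensor
#'
#' Concatenates, for every template residue i and query residue j, the
#' template profile row, query profile row, template observed features,
#' template and query predicted features, and the eigen-pair channel vector
#' into the fixed 77-channel layout.
#'
#' @param profT,profQ L x 20 profiles.
#' @param obsT L_T x 13 observed template features.
#' @param predT,predQ L x 8 predicted features.
#' @param eigen L_T x L_Q x 8 eigen-pair array.
#' @return `pair_feature_tensor`: an L_T x L_Q x 77 array with attribute
#'   `channel_layout`.
#' @export
assemble_pair_tensor <- function(profT, profQ, obsT, predT, predQ, eigen) {
  LT <- nrow(profT); LQ <- nrow(profQ)
  check_block <- function(x, nr, nc, name) {
    if (nrow(x) != nr || ncol(x) != nc)
      stop_format("feature block '%s' is %d x %d, expected %d x %d",
                  name, nrow(x), ncol(x), nr, nc)
  }
  check_block(profT, LT, 20, "template profile")
  check_block(profQ, LQ, 20, "query profile")
  check_block(obsT, LT, 13, "template observed")
  check_block(predT, LT, 8, "template predicted")
  check_block(predQ, LQ, 8, "query predicted")
  if (!all(dim(eigen) == c(LT, LQ, 8)))
    stop_format("feature block 'eigen' has dim %s, expected %d x %d x 8",
                paste(dim(eigen), collapse = " x "), LT, LQ)
  x <- array(0, dim = c(LT, LQ, N_CHANNELS))
  # broadcast per-residue blocks across the other axis
  for (c in 1:20) x[, , c] <- matrix(profT[, c], LT, LQ)
  for (c in 1:20) x[, , 20 + c] <- matrix(profQ[, c], LT, LQ, byrow = TRUE)
  for (c in 1:13) x[, , 40 + c] <- matrix(obsT[, c], LT, LQ)
  for (c in 1:8) x[, , 53 + c] <- matrix(predT[, c], LT, LQ)
  for (c in 1:8) x[, , 61 + c] <- matrix(predQ[, c], LT, LQ, byrow = TRUE)
  x[, , 70:77] <- eigen
  if (!all(is.finite(x))) stop_format("pair tensor contains non-finite values")
  attr(x, "channel_layout") <- channel_layout()
  class(x) <- c("pair_feature_tensor", class(x))
  x
}

#' @rdname assemble_pair_tensor
#' @export
channel_layout <- function() {
  list(template_profile = 1:20, query_profile = 21:40,
       template_observed = 41:53, template_predicted = 54:61,
       query_predicted = 62:69, eigen_pair = 70:77)
}

#' Serialize a pair tensor to a flat binary array plus JSON sidecar
#'
#' The array is written as little-endian doubles in R's column-major order;
#' the sidecar records dimensions and the channel layout.
#'
#' @param x `pair_feature_tensor`.
#' @param path output path for the binary array; the sidecar is
#'   `paste0(path, ".json")`.
#' @return Invisibly, `path`.
#' @export
write_pair_tensor <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(unclass(x)), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(dim = dim(x), channel_layout = channel_layout()),
    paste0(path, ".json"), auto_unbox = FALSE
  )
  invisible(path)
}

#' @rdname write_pair_tensor
#' @export
read_pair_tensor <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "double", n = n, size = 8, endian = "little")
  x <- array(v, dim = meta$dim)
  attr(x, "channel_layout") <- channel_layout()
  class(x) <- c("pair_feature_tensor", class(x))
  x
}
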