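#' Protein record
#'
#' A protein sequence with optional per-residue C-alpha / C-beta coordinates
#' (Angstrom). For glycine, which has no C-beta atom, the C-alpha position is
#' substituted so that C-beta contact geometry is defined for every residue.
#'
#' @param id character identifier.
#' @param sequence character scalar over the 20-letter amino-acid alphabet
#'   plus `X` (unknown).
#' @param ca_coords optional L x 3 numeric matrix of C-alpha coordinates.
#' @param cb_coords optional L x 3 numeric matrix of C-beta coordinates
#'   (C-alpha substituted for Gly).
#' @param chain_id optional chain identifier.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, ca_coords = NULL, cb_coords = NULL,
                           chain_id = NULL) {
  sequence <- toupper(gsub("\\*", "", sequence))
  bad <- setdiff(strsplit(sequence, "")[[1]], c(AA_ALPHABET, "X"))
  if (length(bad) > 0)
    stop_format("invalid amino-acid character(s) in '%s': %s",
                id, paste(unique(bad), collapse = ", "))
  L <- nchar(sequence)
  for (nm in c("ca_coords", "cb_coords")) {
    m <- get(nm)
    if (!is.null(m)) {
      m <- as.matrix(m)
      if (nrow(m) != L || ncol(m) != 3)
        stop_format("%s must be a %d x 3 matrix for '%s'", nm, L, id)
      if (!all(is.finite(m)))
        stop_format("%s contains non-finite values for '%s'", nm, id)
      assign(nm, m)
    }
  }
  structure(
    list(id = id, sequence = sequence, ca_coords = ca_coords,
         cb_coords = cb_coords, chain_id = chain_id),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (L = %d)%s\n", x$id, nchar(x$sequence),
              if (is.null(x$ca_coords)) "" else ", with coordinates"))
  invisible(x)
}

#' @export
length.protein_record <- function(x) nchar(x$sequence)

#' Multiple sequence alignment
#'
#' A rectangular alignment whose first row is the ungapped query sequence;
#' all rows share the query's length (A3M insertion columns are removed at
#' read time).
#'
#' @param query_id identifier of the query (first) sequence.
#' @param rows character vector of aligned rows over amino acids plus `-`.
#' @return An object of class `protein_msa`.
#' @export
protein_msa <- function(query_id, rows) {
  if (length(rows) < 1) stop_format("MSA must contain at least one row")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop_format("MSA row %d has length %d, expected %d",
                bad, widths[bad], widths[1])
  }
  rows <- unname(toupper(rows))
  if (grepl("-", rows[1], fixed = TRUE))
    stop_format("first MSA row (query) must be ungapped")
  bad <- setdiff(unique(strsplit(paste(rows, collapse = ""), "")[[1]]),
                 c(AA_ALPHABET, "X", "-"))
  if (length(bad) > 0)
    stop_format("invalid MSA character(s): %s", paste(bad, collapse = ", "))
  structure(list(query_id = query_id, rows = rows), class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("<protein_msa> query %s: %d rows x %d columns\n",
              x$query_id, length(x$rows), nchar(x$rows[1])))
  invisible(x)
}

#' Per-residue annotation table
#'
#' Holds observed (DSSP-like) or predicted sequential structural annotations:
#' 8- and 3-state secondary structure, relative solvent accessibility in
#' [0, 1], backbone dihedrals phi/psi in degrees (NA at chain termini),
#' and predicted interface / disorder probabilities. Any column may be
#' absent depending on the source.
#'
#' @param df data.frame with any of the columns `ss8`, `ss3`, `rsa`, `phi`,
#'   `psi`, `interface_prob`, `disorder_prob`.
#' @return An object of class `annotation_table` (a validated data.frame).
#' @export
annotation_table <- function(df) {
  df <- as.data.frame(df)
  if (!is.null(df$ss8)) {
    bad <- setdiff(unique(df$ss8), SS8_STATES)
    if (length(bad) > 0)
      stop_format("invalid ss8 state(s): %s", paste(bad, collapse = ", "))
  }
  if (!is.null(df$ss3)) {
    bad <- setdiff(unique(df$ss3), SS3_STATES)
    if (length(bad) > 0)
      stop_format("invalid ss3 state(s): %s", paste(bad, collapse = ", "))
  }
  for (col in c("rsa", "interface_prob", "disorder_prob")) {
    v <- df[[col]]
    if (!is.null(v) && any(!is.na(v) & (v < 0 | v > 1)))
      stop_format("column '%s' must lie in [0, 1]", col)
  }
  for (col in c("phi", "psi")) {
    v <- df[[col]]
    if (!is.null(v) && any(!is.na(v) & (v < -180 | v > 180)))
      stop_format("column '%s' must lie in [-180, 180] degrees", col)
  }
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Reference alignment with local TM-score weights
#'
#' A monotone list of aligned (template, query) residue index pairs with
#' per-pair conservation weights in [0, 1]. Indices are 1-based inside R;
#' on-disk TSV interchange uses 0-based indices.
#'
#' @param pairs integer matrix with columns `t` and `q`, strictly increasing
#'   in both coordinates.
#' @param weights numeric vector in [0, 1], one per pair (default all 1).
#' @return An object of class `reference_alignment`.
#' @export
reference_alignment <- function(pairs, weights = NULL) {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("t", "q")))
  n <- nrow(pairs)
  if (n > 1) {
    dt <- diff(pairs[, 1]); dq <- diff(pairs[, 2])
    if (any(dt <= 0) || any(dq <= 0))
      stop_format("alignment pairs must be strictly increasing in both indices")
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n)
    stop_format("weights length (%d) must equal number of pairs (%d)",
                length(weights), n)
  if (n > 0 && (any(weights < 0) || any(weights > 1)))
    stop_format("weights must lie in [0, 1]")
  structure(list(pairs = pairs, weights = as.numeric(weights)),
            class = "reference_alignment")
}

#' @export
print.reference_alignment <- function(x, ...) {
  cat(sprintf("<reference_alignment> %d aligned pairs, mean weight %.3f\n",
              nrow(x$pairs),
              if (nrow(x$pairs) > 0) mean(x$weights) else NA_real_))
  invisible(x)
}
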