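# Readers and writers for the external formats the engine touches:
# FASTA, A3M / aligned FASTA, PDB (coordinate subset), annotation TSV,
# square matrix files, PIR and TSV alignments.

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return List of [protein_record] in file order; sequences are upper-cased
#'   and trailing `*` stop characters are stripped.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_format("malformed FASTA '%s': %s",
                                                  path, conditionMessage(e)))
  if (length(set) == 0) stop_format("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- unname(as.character(set))
  lapply(seq_along(set), function(i) protein_record(ids[i], seqs[i]))
}

#' Read a multiple sequence alignment
#'
#' In the `a3m` dialect lowercase letters mark insertions relative to the
#' query and are removed, so every row is reduced to the query's columns.
#' In the `aligned_fasta` dialect rows are taken as-is.
#'
#' @param path alignment file path.
#' @param dialect `"a3m"` or `"aligned_fasta"`.
#' @return A [protein_msa].
#' @export
read_msa <- function(path, dialect = c("a3m", "aligned_fasta")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format("file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_format("malformed MSA '%s': %s",
                                                  path, conditionMessage(e)))
  if (length(set) == 0) stop_format("empty MSA file: %s", path)
  rows <- as.character(set)
  if (dialect == "a3m") {
    # remove insertion states (lowercase) and whitespace; '.' is an
    # insertion gap in some a3m emitters
    rows <- gsub("[a-z.[:space:]]", "", rows)
  }
  widths <- nchar(rows)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop_format("MSA row %d has normalized length %d, expected %d (%s)",
                bad, widths[bad], widths[1], path)
  }
  protein_msa(sub("\\s.*$", "", names(set)[1]), rows)
}

#' Read one chain of a PDB file as a protein record
#'
#' Only the first model is used. Residues lacking a C-alpha atom are dropped
#' with a warning; alternate locations resolve to the highest occupancy;
#' HETATM records are ignored. Glycine (and any residue lacking a C-beta)
#' takes its C-alpha position as C-beta.
#'
#' @param path PDB file path.
#' @param chain chain identifier to extract.
#' @return A [protein_record] with `ca_coords` and `cb_coords`.
#' @export
read_structure <- function(path, chain) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  chains <- unique(at$chain)
  if (!(chain %in% chains))
    stop_format("chain '%s' not found in %s; available: %s",
                chain, path, paste(chains, collapse = ", "))
  at <- at[at$chain == chain, , drop = FALSE]
  # residue identity = (resno, insert) in order of appearance
  ins <- ifelse(is.na(at$insert), "", at$insert)
  rid <- paste(at$resno, ins, sep = "_")
  rid <- factor(rid, levels = unique(rid))
  pick_atom <- function(sub, name) {
    sel <- sub[sub$elety == name, , drop = FALSE]
    if (nrow(sel) == 0) return(NULL)
    sel <- sel[which.max(ifelse(is.na(sel$o), 1, sel$o)), , drop = FALSE]
    c(sel$x, sel$y, sel$z)
  }
  ca <- list(); cb <- list(); seq3 <- character(0); dropped <- 0L
  for (lev in levels(rid)) {
    sub <- at[rid == lev, , drop = FALSE]
    p_ca <- pick_atom(sub, "CA")
    if (is.null(p_ca)) { dropped <- dropped + 1L; next }
    p_cb <- pick_atom(sub, "CB")
    if (is.null(p_cb)) p_cb <- p_ca  # Gly: C-alpha substituted
    ca[[length(ca) + 1L]] <- p_ca
    cb[[length(cb) + 1L]] <- p_cb
    seq3 <- c(seq3, sub$resid[1])
  }
  if (dropped > 0)
    warning(sprintf("%s chain %s: dropped %d residue(s) without C-alpha",
                    path, chain, dropped))
  if (length(ca) == 0) stop_format("chain '%s' in %s has no C-alpha atoms",
                                   chain, path)
  aa1 <- bio3d::aa321(seq3)
  aa1[is.na(aa1) | !(aa1 %in% AA_ALPHABET)] <- "X"
  protein_record(
    id = sub("\\.pdb$", "", basename(path)),
    sequence = paste(aa1, collapse = ""),
    ca_coords = do.call(rbind, ca),
    cb_coords = do.call(rbind, cb),
    chain_id = chain
  )
}

#' Read a per-residue annotation TSV
#'
#' One row per residue with named columns among `ss8`, `ss3`, `rsa`, `phi`,
#' `psi`, `interface_prob`, `disorder_prob`. Missing dihedrals (termini) may
#' be encoded as `NA`.
#'
#' @param path TSV file path.
#' @return An [annotation_table].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  annotation_table(df)
}

#' Read a square numeric matrix (contact map) from a text file
#'
#' Accepts whitespace- or comma-delimited grids. Asymmetric input beyond
#' 1e-6 is symmetrized as `(M + t(M)) / 2` with a warning.
#'
#' @param path matrix file path.
#' @return A square numeric matrix.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          strip.white = TRUE)
  m <- as.matrix(df)
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop_format("matrix in %s is %d x %d, expected square",
                path, nrow(m), ncol(m))
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6) {
    warning(sprintf("matrix in %s asymmetric by %.3g; symmetrizing",
                    path, asym))
    m <- (m + t(m)) / 2
  }
  m
}

#' Write a template-query alignment to PIR or TSV
#'
#' TSV rows carry `(template_index, query_index, probability)` with 0-based
#' indices (interchange convention); PIR is the two-sequence gapped layout
#' used to hand alignments to comparative-modelling tools, with 1-based
#' display. An empty alignment is written as a 0-row TSV; PIR output for an
#' empty alignment is refused with a warning since a fully unaligned PIR
#' entry is meaningless.
#'
#' @param result an `alignment_result` from [mac_align()].
#' @param template,query [protein_record]s the indices refer to.
#' @param path output file path.
#' @param format `"pir"` or `"tsv"`.
#' @param probs optional numeric vector of per-pair probabilities for TSV.
#' @return Invisibly, the path (or `NULL` if PIR output was skipped).
#' @export
write_alignment <- function(result, template, query, path,
                            format = c("tsv", "pir"), probs = NULL) {
  format <- match.arg(format)
  pairs <- result$pairs
  n <- nrow(pairs)
  if (n > 0) {
    if (max(pairs[, 1]) > length(template) || max(pairs[, 2]) > length(query))
      stop_format("alignment indices exceed protein lengths")
    if (n > 1 && (any(diff(pairs[, 1]) <= 0) || any(diff(pairs[, 2]) <= 0)))
      stop_format("internal error: non-monotone alignment pairs")
  }
  if (format == "tsv") {
    df <- data.frame(
      template_index = pairs[, 1] - 1L,
      query_index = pairs[, 2] - 1L,
      probability = if (is.null(probs)) rep(NA_real_, n) else probs
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (n == 0) {
    warning("empty alignment: PIR output skipped")
    return(invisible(NULL))
  }
  rows <- gapped_rows(pairs, template$sequence, query$sequence)
  lines <- c(
    sprintf(">P1;%s", template$id),
    sprintf("structure:%s:%d:%s:%d:%s::::", template$id, pairs[1, 1],
            template$chain_id %||% "A", pairs[n, 1],
            template$chain_id %||% "A"),
    paste0(rows$t, "*"),
    sprintf(">P1;%s", query$id),
    sprintf("sequence:%s:%d::%d:::::", query$id, pairs[1, 2], pairs[n, 2]),
    paste0(rows$q, "*")
  )
  writeLines(lines, path)
  invisible(path)
}

# Build the two gapped strings of a pairwise alignment restricted to the
# aligned block (local alignment: flanks are not shown). Between consecutive
# matched pairs, unmatched template residues align to '-' first, then
# unmatched query residues.
gapped_rows <- function(pairs, tseq, qseq) {
  tt <- strsplit(tseq, "")[[1]]
  qq <- strsplit(qseq, "")[[1]]
  out_t <- character(0); out_q <- character(0)
  prev_t <- pairs[1, 1] - 1L; prev_q <- pairs[1, 2] - 1L
  for (r in seq_len(nrow(pairs))) {
    ti <- pairs[r, 1]; qi <- pairs[r, 2]
    if (ti - prev_t > 1L) {
      ins <- (prev_t + 1L):(ti - 1L)
      out_t <- c(out_t, tt[ins]); out_q <- c(out_q, rep("-", length(ins)))
    }
    if (qi - prev_q > 1L) {
      ins <- (prev_q + 1L):(qi - 1L)
      out_t <- c(out_t, rep("-", length(ins))); out_q <- c(out_q, qq[ins])
    }
    out_t <- c(out_t, tt[ti]); out_q <- c(out_q, qq[qi])
    prev_t <- ti; prev_q <- qi
  }
  list(t = paste(out_t, collapse = ""), q = paste(out_q, collapse = ""))
}

#' Read an alignment TSV written by [write_alignment()]
#'
#' @param path TSV path with 0-based `template_index`, `query_index` columns.
#' @return An `alignment_result`-like list with 1-based `pairs` and the
#'   stored probabilities.
#' @export
read_alignment_tsv <- function(path) {
  df <- utils::read.delim(path)
  pairs <- cbind(t = as.integer(df$template_index) + 1L,
                 q = as.integer(df$query_index) + 1L)
  list(pairs = pairs, probs = df$probability)
}

#' Write / read a reference alignment as TSV
#'
#' Columns `t_index`, `q_index` (0-based on disk), `weight`.
#'
#' @param ref a [reference_alignment].
#' @param path TSV path.
#' @return `write_reference_tsv` returns the path invisibly;
#'   `read_reference_tsv` returns a [reference_alignment].
#' @export
write_reference_tsv <- function(ref, path) {
  df <- data.frame(t_index = ref$pairs[, 1] - 1L,
                   q_index = ref$pairs[, 2] - 1L,
                   weight = ref$weights)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_tsv
#' @export
read_reference_tsv <- function(path) {
  df <- utils::read.delim(path)
  reference_alignment(cbind(df$t_index + 1L, df$q_index + 1L), df$weight)
}
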