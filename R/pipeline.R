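# Threading orchestration: precompute per-template features into a library,
# align a query against every template, rank by optimal MAC score, and
# evaluate predicted alignments against references.

#' Per-template precomputed feature entry
#'
#' @param id unique template identifier.
#' @param record template [protein_record] with coordinates.
#' @param profile L x 20 sequence profile.
#' @param observed L x 13 observed structural features.
#' @param predicted L x 8 predicted structural features.
#' @param eigen [eigen_embedding] of the observed contact map.
#' @return A `template_entry` list.
#' @export
template_entry <- function(id, record, profile, observed, predicted, eigen) {
  L <- length(record)
  if (nrow(profile) != L || nrow(observed) != L || nrow(predicted) != L ||
      ncol(eigen$vectors) != L)
    stop_format("template '%s': feature lengths disagree with sequence", id)
  structure(list(id = id, record = record, profile = profile,
                 observed = observed, predicted = predicted, eigen = eigen),
            class = "template_entry")
}

# Compute a template_entry from raw per-template inputs.
make_template_entry <- function(id, record, msa, ann) {
  template_entry(
    id = id,
    record = record,
    profile = profile_from_msa(msa),
    observed = observed_template_features(record, ann),
    predicted = predicted_features(ann),
    eigen = eigen_embedding(contact_map_from_coords(record))
  )
}

#' Template library container
#'
#' @param entries list of [template_entry()] with unique ids.
#' @return A `template_library`.
#' @export
template_library <- function(entries) {
  ids <- vapply(entries, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_format("duplicate template ids in library")
  if (length(entries) == 0) stop_format("empty template library")
  structure(list(entries = entries, ids = ids), class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library> %d templates\n", length(x$entries)))
  invisible(x)
}

#' Build a template library from a directory of per-template files
#'
#' For every `<id>.pdb` in `input_dir`, reads the structure (chain A unless
#' stated in `<id>.chain`), the MSA `<id>.msa` (aligned FASTA) or `<id>.a3m`,
#' and annotations `<id>_ann.tsv`, precomputes features once and serializes
#' them under `out_dir` with a JSON manifest (md5 content hash, so an
#' unchanged rebuild is idempotent). Templates failing feature extraction
#' are skipped with a warning.
#'
#' @param input_dir directory of per-template inputs.
#' @param out_dir output directory for the serialized library.
#' @return A `template_library` (also written to
#'   `file.path(out_dir, "library.rds")`).
#' @export
build_library <- function(input_dir, out_dir) {
  pdbs <- sort(list.files(input_dir, pattern = "\\.pdb$", full.names = TRUE))
  if (length(pdbs) == 0) stop_format("no PDB files in %s", input_dir)
  entries <- list()
  for (pdb in pdbs) {
    id <- sub("\\.pdb$", "", basename(pdb))
    entry <- tryCatch({
      chain_file <- file.path(input_dir, paste0(id, ".chain"))
      chain <- if (file.exists(chain_file)) readLines(chain_file)[1] else "A"
      record <- read_structure(pdb, chain)
      msa_path <- file.path(input_dir, paste0(id, ".msa"))
      a3m_path <- file.path(input_dir, paste0(id, ".a3m"))
      msa <- if (file.exists(a3m_path)) read_msa(a3m_path, "a3m")
             else read_msa(msa_path, "aligned_fasta")
      ann <- read_annotation(file.path(input_dir, paste0(id, "_ann.tsv")))
      make_template_entry(id, record, msa, ann)
    }, error = function(e) {
      warning(sprintf("template '%s' skipped: %s", id,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(entry)) entries[[length(entries) + 1L]] <- entry
  }
  lib <- template_library(entries)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lib_path <- file.path(out_dir, "library.rds")
  saveRDS(lib, lib_path)
  manifest <- list(
    n_templates = length(lib$entries),
    ids = lib$ids,
    hash = unname(tools::md5sum(lib_path))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  lib
}

#' Assemble query-side inputs for threading
#'
#' @param record query [protein_record] (coordinates optional).
#' @param profile L x 20 profile (e.g. [profile_from_msa()]).
#' @param predicted L x 8 predicted features ([predicted_features()]).
#' @param contacts predicted [contact_map] (probabilities) for the query.
#' @return A `query_inputs` list with the eigen embedding precomputed.
#' @export
query_inputs <- function(record, profile, predicted, contacts) {
  L <- length(record)
  if (nrow(profile) != L || nrow(predicted) != L ||
      nrow(contacts$m) != L)
    stop_format("query feature lengths disagree with sequence")
  structure(list(record = record, profile = profile, predicted = predicted,
                 eigen = eigen_embedding(contacts)),
            class = "query_inputs")
}

#' Thread a query against a template library
#'
#' For each template: assemble the pair tensor, predict the aligning
#' probability matrix, run the Maximum Accuracy alignment, and record the
#' optimal score. Templates are ranked by raw MAC score, descending.
#'
#' @param query a [query_inputs()].
#' @param library a [template_library].
#' @param scorer a trained `threader_scorer`.
#' @param alpha MAC greediness penalty (default 0.3).
#' @param top_n number of alignments to retain in full (default 5).
#' @return A `threading_report`: list with `ranking` data.frame
#'   (template_id, mac_score, n_pairs) sorted by score, and `alignments`
#'   (named list of `alignment_result` for the top_n templates).
#' @export
thread_query <- function(query, library, scorer, alpha = 0.3, top_n = 5L) {
  if (length(library$entries) == 0) stop_format("empty template library")
  results <- lapply(library$entries, function(entry) {
    eig <- eigen_pair_features(entry$eigen, query$eigen)
    x <- assemble_pair_tensor(entry$profile, query$profile, entry$observed,
                              entry$predicted, query$predicted, eig)
    pm <- predict_matrix(scorer, x)
    mac_align(pm$p, alpha = alpha)
  })
  scores <- vapply(results, `[[`, numeric(1), "score")
  ord <- order(-scores)
  ranking <- data.frame(
    rank = seq_along(ord),
    template_id = library$ids[ord],
    mac_score = round(scores[ord], 6),
    n_pairs = vapply(results[ord], function(r) nrow(r$pairs), integer(1))
  )
  keep <- ord[seq_len(min(top_n, length(ord)))]
  alignments <- stats::setNames(results[keep], library$ids[keep])
  structure(list(ranking = ranking, alignments = alignments,
                 alpha = alpha),
            class = "threading_report")
}

#' @export
print.threading_report <- function(x, ...) {
  cat(sprintf("<threading_report> %d templates ranked (alpha = %g)\n",
              nrow(x$ranking), x$alpha))
  print(utils::head(x$ranking, 10))
  invisible(x)
}

#' Evaluate predicted alignments against references
#'
#' Reports aligned-pair precision / recall / F1 and, when both coordinate
#' sets are supplied, the TM-score and GDT of the alignment-implied model:
#' template C-alpha coordinates copied onto the aligned query positions and
#' compared with the query's true coordinates. This is an alignment-quality
#' proxy for full model building, which requires external comparative-
#' modelling software.
#'
#' @param pred `alignment_result` (or list of them).
#' @param ref [reference_alignment] (or list matching `pred`).
#' @param caT,caQ optional template / true-query C-alpha coordinates.
#' @return One-row data.frame per prediction: precision, recall, f1 and
#'   (if coordinates given) tm_score, gdt.
#' @export
evaluate_alignment <- function(pred, ref, caT = NULL, caQ = NULL) {
  if (inherits(pred, "alignment_result")) {
    pred <- list(pred); ref <- list(ref)
    caT <- list(caT); caQ <- list(caQ)
  }
  rows <- lapply(seq_along(pred), function(k) {
    acc <- pair_accuracy(pred[[k]], ref[[k]])
    row <- data.frame(precision = acc$precision, recall = acc$recall,
                      f1 = acc$f1, tm_score = NA_real_, gdt = NA_real_)
    ct <- caT[[k]]; cq <- caQ[[k]]
    pr <- pred[[k]]$pairs
    if (!is.null(ct) && !is.null(cq) && nrow(pr) >= 3) {
      # "model" = template backbone copied through the alignment
      LQ <- nrow(cq)
      row$tm_score <- tm_score(cbind(pr[, 2], pr[, 1]), cq, ct, L_norm = LQ)
      row$gdt <- gdt(cbind(pr[, 2], pr[, 1]), cq, ct, L_norm = LQ)
    }
    row
  })
  do.call(rbind, rows)
}

#' Build an in-memory synthetic template library plus a matching query
#'
#' Convenience wrapper used by tests and examples: generates `n_templates`
#' unrelated toy templates, derives a query from the template at
#' `source_index`, and returns the library, the query inputs and the
#' ground-truth reference alignment.
#'
#' @param n_templates library size.
#' @param source_index which template the query is derived from.
#' @param spec [pair_spec()] controlling the derivation.
#' @param seed master seed.
#' @return List with `library`, `query`, `ref`, `source_id`, and the true
#'   query record.
#' @export
synthetic_library <- function(n_templates = 5L, source_index = 1L,
                              spec = pair_spec(), seed = 1L) {
  stopifnot(source_index >= 1, source_index <= n_templates)
  templates <- lapply(seq_len(n_templates), function(k)
    generate_structure(spec$template_length, derive_seed(seed, 100L + k)))
  sp <- spec
  sp$seed <- derive_seed(seed, 7L)
  src <- templates[[source_index]]
  # regenerate the source pair through generate_pair-style derivation
  qres <- derive_query(src, sp)
  profs <- synthesize_profiles(src$record, qres$record, qres$ref, sp)
  entries <- lapply(seq_len(n_templates), function(k) {
    tpl <- templates[[k]]
    prof <- if (k == source_index) profs$profT
            else with_seed(derive_seed(seed, 300L + k), {
              sp_k <- sp
              t(vapply(strsplit(tpl$record$sequence, "")[[1]], function(a) {
                alpha <- rep(0.3, 20)
                j <- match(a, AA_ALPHABET)
                if (!is.na(j)) alpha[j] <- alpha[j] + sp_k$profile_concentration
                g <- stats::rgamma(20, shape = alpha)
                g / sum(g)
              }, numeric(20)))
            })
    template_entry(
      id = sprintf("tpl_%02d", k),
      record = tpl$record,
      profile = prof,
      observed = observed_template_features(tpl$record, tpl$ann),
      predicted = predicted_features(tpl$ann),
      eigen = eigen_embedding(contact_map_from_coords(tpl$record))
    )
  })
  query <- query_inputs(
    record = qres$record,
    profile = profs$profQ,
    predicted = predicted_features(qres$ann),
    contacts = soft_contact_map(qres$record)
  )
  list(library = template_library(entries), query = query, ref = qres$ref,
       source_id = sprintf("tpl_%02d", source_index),
       query_record = qres$record,
       source_record = src$record)
}
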