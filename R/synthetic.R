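# Synthetic template-query pair generator. Toy backbones are assembled from
# ideal helix / strand / coil segments; a query is derived from a template
# by indels, coordinate noise and sequence substitution, so the surviving
# residue correspondence is a ground-truth reference alignment. Profiles
# with a shared planted signal at aligned columns emulate what an MSA
# pipeline would provide. Everything is driven by explicit seeds.

#' Specification for one synthetic template-query pair
#'
#' Defaults are the package's standard desk-scale study conditions:
#' 60-residue templates, 10% indels, 10% substitutions, 0.3 Angstrom
#' coordinate noise and a strong (concentration 100) planted profile
#' signal.
#'
#' @param template_length template length (>= 10).
#' @param indel_rate per-residue deletion/insertion rate in [0, 0.5).
#' @param substitution_rate per-residue mutation rate in [0, 1].
#' @param coord_noise_sd isotropic coordinate noise, Angstrom.
#' @param profile_concentration Dirichlet-like concentration of profile
#'   columns on the residue identity (> 0); larger = stronger signal.
#' @param seed integer seed.
#' @return A `pair_spec` list.
#' @export
pair_spec <- function(template_length = 60L, indel_rate = 0.1,
                      substitution_rate = 0.1, coord_noise_sd = 0.3,
                      profile_concentration = 100, seed = 1L) {
  stopifnot(template_length >= 10, indel_rate >= 0, indel_rate < 0.5,
            substitution_rate >= 0, substitution_rate <= 1,
            coord_noise_sd >= 0, profile_concentration > 0)
  structure(list(template_length = as.integer(template_length),
                 indel_rate = indel_rate,
                 substitution_rate = substitution_rate,
                 coord_noise_sd = coord_noise_sd,
                 profile_concentration = profile_concentration,
                 seed = as.integer(seed)),
            class = "pair_spec")
}

random_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Ideal local segment geometries (first residue at the origin).
segment_coords <- function(type, n) {
  i <- seq_len(n) - 1
  switch(type,
    H = cbind(2.3 * cos(i * 100 * pi / 180) - 2.3,
              2.3 * sin(i * 100 * pi / 180),
              1.5 * i),
    E = cbind(3.3 * i, 0.8 * ((-1)^i - 1) / 2 * 2, 0 * i),
    stop("coil segments are generated by random walk")
  )
}

#' Generate a toy protein structure with annotations
#'
#' The backbone is a chain of ideal helix (rise 1.5 Angstrom, 100 degree
#' turn), strand (rise 3.3 Angstrom) and random-coil (step 3.8 Angstrom,
#' excluded-volume rejection at 3.0 Angstrom) segments of length 4-15,
#' joined by 3.8 Angstrom steps under random rotations. C-beta atoms sit
#' 1.5 Angstrom off the local backbone axis (glycine: C-beta = C-alpha).
#' Annotations carry the segment's secondary-structure state, canonical
#' dihedrals with noise, and sampled rsa / interface / disorder tracks, so
#' the same table serves the observed and predicted feature encoders.
#'
#' @param length number of residues (>= 10).
#' @param seed integer seed; identical seeds give identical structures.
#' @param max_attempts cap on coil rejection sampling before erroring.
#' @return List with `record` ([protein_record]) and `ann`
#'   ([annotation_table] with a `segment` attribute).
#' @export
generate_structure <- function(length, seed = 1L, max_attempts = 1e4) {
  stopifnot(length >= 10)
  with_seed(seed, {
    # segment plan
    types <- character(0); lens <- integer(0); total <- 0L
    while (total < length) {
      tp <- sample(c("H", "E", "C"), 1, prob = c(0.45, 0.3, 0.25))
      ln <- sample(4:15, 1)
      ln <- min(ln, length - total)
      types <- c(types, tp); lens <- c(lens, ln); total <- total + ln
    }
    coords <- matrix(numeric(0), 0, 3)
    attempts <- 0L
    clash <- function(pt, exclude_last = 1L) {
      n <- nrow(coords)
      if (n <= exclude_last) return(FALSE)
      keep <- coords[seq_len(n - exclude_last), , drop = FALSE]
      any(rowSums(sweep(keep, 2, pt)^2) < 9)  # 3.0 A squared
    }
    place_step <- function(from) {
      repeat {
        attempts <<- attempts + 1L
        if (attempts > max_attempts)
          stop_format("structure generation exceeded %d attempts",
                      as.integer(max_attempts))
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        pt <- from + 3.8 * u
        if (!clash(pt)) return(pt)
      }
    }
    for (s in seq_along(types)) {
      n <- lens[s]
      start <- if (nrow(coords) == 0) c(0, 0, 0)
               else place_step(coords[nrow(coords), ])
      if (types[s] == "C") {
        seg <- matrix(0, n, 3)
        seg[1, ] <- start
        if (n > 1) {
          coords <- rbind(coords, seg[1, , drop = FALSE])
          for (r in 2:n) {
            pt <- place_step(coords[nrow(coords), ])
            seg[r, ] <- pt
            coords <- rbind(coords, matrix(pt, 1, 3))
          }
          coords <- coords[seq_len(nrow(coords) - n), , drop = FALSE]
        }
      } else {
        # retry rotations until the rigid segment is clash-free
        local <- segment_coords(types[s], n)
        repeat {
          attempts <- attempts + 1L
          if (attempts > max_attempts)
            stop_format("structure generation exceeded %d attempts",
                        as.integer(max_attempts))
          R <- random_rotation()
          seg <- sweep(local %*% t(R), 2, start, "+")
          n_prev <- nrow(coords)
          ok <- TRUE
          if (n_prev > 1 && n > 1) {
            prev <- coords[seq_len(n_prev - 1), , drop = FALSE]
            later <- seg[2:n, , drop = FALSE]
            dd <- outer(rowSums(prev^2), rep(1, nrow(later))) +
              outer(rep(1, nrow(prev)), rowSums(later^2)) -
              2 * prev %*% t(later)
            ok <- all(dd > 9)
          }
          if (ok) break
        }
      }
      coords <- rbind(coords, seg)
    }
    segment <- rep(types, lens)
    L <- nrow(coords)
    sequence <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    # C-beta 1.5 A along the local normal; glycine keeps C-alpha
    cb <- coords
    aa <- strsplit(sequence, "")[[1]]
    for (i in seq_len(L)) {
      if (aa[i] == "G") next
      lo <- max(1, i - 1); hi <- min(L, i + 1)
      v <- coords[i, ] - (coords[lo, ] + coords[hi, ]) / 2
      if (sqrt(sum(v^2)) < 1e-6) {
        ref <- coords[i, ] - coords[lo, ]
        v <- c(-ref[2], ref[1], 0)
        if (sqrt(sum(v^2)) < 1e-6) v <- c(1, 0, 0)
      }
      cb[i, ] <- coords[i, ] + 1.5 * v / sqrt(sum(v^2))
    }
    record <- protein_record(sprintf("synth_%d", seed), sequence,
                             ca_coords = coords, cb_coords = cb)
    canon <- list(H = c(-60, -45), E = c(-120, 130), C = c(NA, NA))
    phi <- numeric(L); psi <- numeric(L)
    for (i in seq_len(L)) {
      cn <- canon[[segment[i]]]
      phi[i] <- if (is.na(cn[1])) stats::runif(1, -180, 180)
                else cn[1] + stats::rnorm(1, sd = 5)
      psi[i] <- if (is.na(cn[2])) stats::runif(1, -180, 180)
                else cn[2] + stats::rnorm(1, sd = 5)
    }
    phi <- pmin(pmax(phi, -180), 180); psi <- pmin(pmax(psi, -180), 180)
    phi[1] <- NA; psi[L] <- NA  # chain termini
    ann <- annotation_table(data.frame(
      ss8 = segment,  # H/E/C are valid 8-state letters
      ss3 = segment,
      rsa = stats::runif(L),
      phi = phi, psi = psi,
      interface_prob = stats::runif(L),
      disorder_prob = ifelse(segment == "C", stats::runif(L, 0.3, 0.9),
                             stats::runif(L, 0, 0.3))
    ))
    attr(ann, "segment") <- segment
    attr(ann, "segment_id") <- rep(seq_along(types), lens)
    list(record = record, ann = ann)
  })
}

#' Derive a query from a template with known ground truth
#'
#' Deletes and inserts residues at `indel_rate` (split evenly), perturbs
#' retained coordinates with isotropic Gaussian noise, and mutates the
#' sequence at `substitution_rate`. The surviving (template, query) residue
#' correspondence is returned as the reference alignment, weighted by local
#' TM-scores of the noisy superposition.
#'
#' @param template output of [generate_structure()] (list with `record`,
#'   `ann`).
#' @param spec a [pair_spec()].
#' @return List with `record`, `ann` (query side) and `ref`
#'   ([reference_alignment]).
#' @export
derive_query <- function(template, spec) {
  rec <- template$record; ann <- template$ann
  L <- length(rec)
  with_seed(derive_seed(spec$seed, 17L), {
    keep <- stats::runif(L) >= spec$indel_rate / 2
    if (sum(keep) < 3) stop_format("indels removed (almost) all residues")
    kept_idx <- which(keep)
    aa <- strsplit(rec$sequence, "")[[1]]
    rows <- list()  # each: list(t = template index or NA, ca, cb, aa, ann row)
    add_kept <- function(i) {
      noise <- stats::rnorm(3, sd = spec$coord_noise_sd)
      a <- aa[i]
      if (stats::runif(1) < spec$substitution_rate)
        a <- sample(setdiff(AA_ALPHABET, a), 1)
      list(t = i, ca = rec$ca_coords[i, ] + noise,
           cb = rec$cb_coords[i, ] + noise, aa = a, ann = ann[i, ])
    }
    coil_row <- function(prev_ca) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      ca <- prev_ca + 3.8 * u
      list(t = NA_integer_, ca = ca, cb = ca,
           aa = sample(AA_ALPHABET, 1),
           ann = data.frame(ss8 = "C", ss3 = "C", rsa = stats::runif(1),
                            phi = stats::runif(1, -180, 180),
                            psi = stats::runif(1, -180, 180),
                            interface_prob = stats::runif(1),
                            disorder_prob = stats::runif(1, 0.3, 0.9)))
    }
    for (i in kept_idx) {
      rows[[length(rows) + 1L]] <- add_kept(i)
      if (stats::runif(1) < spec$indel_rate / 2) {
        prev <- rows[[length(rows)]]$ca
        rows[[length(rows) + 1L]] <- coil_row(prev)
      }
    }
    ca <- do.call(rbind, lapply(rows, `[[`, "ca"))
    cb <- do.call(rbind, lapply(rows, `[[`, "cb"))
    qseq <- paste(vapply(rows, `[[`, character(1), "aa"), collapse = "")
    qann <- annotation_table(do.call(rbind, lapply(rows, `[[`, "ann")))
    rownames(qann) <- NULL
    qrec <- protein_record(paste0(rec$id, "_q"), qseq,
                           ca_coords = ca, cb_coords = cb)
    tmap <- vapply(rows, `[[`, integer(1), "t")
    pairs <- cbind(t = tmap[!is.na(tmap)], q = which(!is.na(tmap)))
    ref <- local_tm_weights(reference_alignment(pairs),
                            rec$ca_coords, qrec$ca_coords)
    list(record = qrec, ann = qann, ref = ref)
  })
}

#' Plant correlated sequence profiles for a template-query pair
#'
#' Aligned columns of the two profiles are drawn from one shared
#' distribution concentrated (by `profile_concentration`) on the query's
#' (possibly mutated) residue identity, plus small independent noise;
#' unaligned columns get independent distributions centered on their own
#' residue. Larger concentration gives a stronger aligning signal.
#'
#' @param template,query [protein_record]s.
#' @param ref [reference_alignment] between them.
#' @param spec a [pair_spec()].
#' @return List with `profT` (L_T x 20) and `profQ` (L_Q x 20), rows on the
#'   simplex.
#' @export
synthesize_profiles <- function(template, query, ref, spec) {
  conc <- spec$profile_concentration
  with_seed(derive_seed(spec$seed, 29L), {
    aaT <- strsplit(template$sequence, "")[[1]]
    aaQ <- strsplit(query$sequence, "")[[1]]
    draw <- function(center_aa) {
      alpha <- rep(0.3, 20)
      k <- match(center_aa, AA_ALPHABET)
      if (!is.na(k)) alpha[k] <- alpha[k] + conc
      g <- stats::rgamma(20, shape = alpha)
      g / sum(g)
    }
    jitter_simplex <- function(p) {
      q <- p + stats::rgamma(20, shape = 0.05)
      q / sum(q)
    }
    profT <- t(vapply(aaT, draw, numeric(20)))
    profQ <- t(vapply(aaQ, draw, numeric(20)))
    pr <- ref$pairs
    for (r in seq_len(nrow(pr))) {
      shared <- draw(aaQ[pr[r, 2]])
      profT[pr[r, 1], ] <- jitter_simplex(shared)
      profQ[pr[r, 2], ] <- jitter_simplex(shared)
    }
    dimnames(profT) <- list(NULL, AA_ALPHABET)
    dimnames(profQ) <- list(NULL, AA_ALPHABET)
    list(profT = profT, profQ = profQ)
  })
}

# Soft "predicted" contact probabilities from coordinates: a logistic in
# the C-beta distance around the 8 A threshold, emulating an imperfect
# contact predictor.
soft_contact_map <- function(record, threshold = 8.0, sharpness = 0.8) {
  d <- as.matrix(stats::dist(record$cb_coords))
  m <- 1 / (1 + exp((d - threshold) / sharpness))
  diag(m) <- 0
  contact_map(m, kind = "predicted_prob")
}

#' Generate one full synthetic training sample
#'
#' Runs the whole feature path: toy template structure, derived query,
#' planted profiles, observed/predicted structural features, observed
#' (template) and soft predicted (query) contact maps, eigen embeddings,
#' the assembled 77-channel pair tensor and the TM-weighted label matrix.
#'
#' @param spec a [pair_spec()].
#' @return Training sample: list with `x`, `w`, `mask`, `ref`, `template`,
#'   `query` (each side a list with `record`, `ann`) and `profiles`.
#' @export
generate_pair <- function(spec = pair_spec()) {
  template <- generate_structure(spec$template_length,
                                 derive_seed(spec$seed, 1L))
  qres <- derive_query(template, spec)
  profs <- synthesize_profiles(template$record, qres$record, qres$ref, spec)
  obsT <- observed_template_features(template$record, template$ann)
  predT <- predicted_features(template$ann)
  predQ <- predicted_features(qres$ann)
  embT <- eigen_embedding(contact_map_from_coords(template$record))
  embQ <- eigen_embedding(soft_contact_map(qres$record))
  eig <- eigen_pair_features(embT, embQ)
  x <- assemble_pair_tensor(profs$profT, profs$profQ, obsT, predT, predQ,
                            eig)
  LT <- length(template$record); LQ <- length(qres$record)
  list(x = x,
       w = label_matrix(qres$ref, LT, LQ),
       mask = matrix(TRUE, LT, LQ),
       ref = qres$ref,
       template = template,
       query = qres,
       profiles = profs,
       spec = spec)
}

#' Generate a dataset of synthetic training samples
#'
#' Per-sample seeds are derived deterministically from the master seed, so
#' the same call reproduces the identical dataset.
#'
#' @param n_pairs number of template-query pairs (>= 1).
#' @param spec base [pair_spec()]; its seed field is overridden per sample.
#' @param seed master seed.
#' @return List with `samples` (list of [generate_pair()] outputs) and
#'   `manifest` (per-sample specs).
#' @export
generate_dataset <- function(n_pairs, spec = pair_spec(), seed = 1L) {
  stopifnot(n_pairs >= 1)
  samples <- vector("list", n_pairs)
  manifest <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    sp <- spec
    sp$seed <- derive_seed(seed, 1000L + k)
    samples[[k]] <- generate_pair(sp)
    manifest[[k]] <- unclass(sp)
  }
  list(samples = samples, manifest = manifest)
}

#' Write a synthetic pair to a dataset directory
#'
#' Emits the on-disk forms every other module consumes: FASTA sequences,
#' PDB-format coordinates, annotation TSVs, the reference alignment TSV and
#' the query's predicted contact map.
#'
#' @param sample output of [generate_pair()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_synthetic_pair <- function(sample, dir, prefix = "pair") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(ext) file.path(dir, paste0(prefix, ext))
  write_pdb_record <- function(rec, path) {
    n <- length(rec)
    xyz <- as.vector(t(rec$ca_coords))
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = seq_len(n),
                     resid = vapply(strsplit(rec$sequence, "")[[1]],
                                    aa_one_to_three, character(1)),
                     elety = rep("CA", n), chain = rep("A", n))
  }
  seqs <- Biostrings::BStringSet(c(sample$template$record$sequence,
                                   sample$query$record$sequence))
  names(seqs) <- c(sample$template$record$id, sample$query$record$id)
  Biostrings::writeXStringSet(seqs, f(".fasta"))
  write_pdb_record(sample$template$record, f("_template.pdb"))
  write_pdb_record(sample$query$record, f("_query.pdb"))
  utils::write.table(sample$template$ann, f("_template_ann.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sample$query$ann, f("_query_ann.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_reference_tsv(sample$ref, f("_ref.tsv"))
  cmq <- soft_contact_map(sample$query$record)
  utils::write.table(cmq$m, f("_query_contacts.txt"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(f(".fasta"), f("_template.pdb"), f("_query.pdb"),
              f("_template_ann.tsv"), f("_query_ann.tsv"), f("_ref.tsv"),
              f("_query_contacts.txt")))
}

aa_one_to_three <- function(a) {
  tbl <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
           G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
           M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
           S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR",
           X = "UNK")
  unname(tbl[a])
}
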