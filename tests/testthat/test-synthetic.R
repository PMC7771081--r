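test_that("toy structures are reproducible with sound backbone geometry", {
  a <- generate_structure(40, seed = 71)
  b <- generate_structure(40, seed = 71)
  expect_identical(a$record$ca_coords, b$record$ca_coords)
  expect_identical(a$record$sequence, b$record$sequence)

  steps <- sqrt(rowSums(diff(a$record$ca_coords)^2))
  expect_true(all(steps >= 3.2 & steps <= 4.2))
  expect_equal(nrow(a$ann), 40L)
  # no steric clashes tighter than the excluded-volume radius between
  # non-adjacent residues
  d <- as.matrix(dist(a$record$ca_coords))
  sep <- abs(outer(1:40, 1:40, "-")) >= 2
  expect_true(all(d[sep] > 2.5))
})

test_that("helical segments show the near-diagonal contact band", {
  # scan a few seeds for a structure containing a long helix segment
  found <- 0L
  for (seed in 72:85) {
    g <- generate_structure(60, seed = seed)
    seg <- attr(g$ann, "segment")
    sid <- attr(g$ann, "segment_id")
    runs <- rle(sid)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    hel <- which(runs$lengths >= 8 & seg[starts] == "H")
    if (length(hel) == 0) next
    found <- found + 1L
    cm <- contact_map_from_coords(g$record)$m
    for (h in hel) {
      # interior residues only: terminal C-betas lean on the junction
      idx <- (starts[h] + 1L):(ends[h] - 1L)
      # i, i+4 contacts present throughout the helix turn ladder
      for (i in idx[seq_len(length(idx) - 4)])
        expect_equal(cm[i, i + 4], 1)
    }
    if (found >= 3L) break
  }
  expect_gte(found, 1L)
})

test_that("derived queries carry exact ground truth", {
  tpl <- generate_structure(50, seed = 73)

  clean <- pair_spec(template_length = 50, indel_rate = 0,
                     substitution_rate = 0, coord_noise_sd = 0, seed = 74)
  q0 <- derive_query(tpl, clean)
  expect_equal(unname(q0$ref$pairs), unname(cbind(1:50, 1:50)))
  expect_equal(q0$ref$weights, rep(1, 50))
  expect_identical(q0$record$sequence, tpl$record$sequence)

  for (sd in 75:78) {
    sp <- pair_spec(template_length = 50, seed = sd)
    q <- derive_query(tpl, sp)
    pr <- q$ref$pairs
    expect_true(all(diff(pr[, 1]) > 0))
    expect_true(all(diff(pr[, 2]) > 0))
    expect_lte(max(pr[, 2]), length(q$record))
    expect_equal(nrow(q$ann), length(q$record))
  }

  noisy <- derive_query(tpl, pair_spec(template_length = 50,
                                       coord_noise_sd = 1.0, seed = 79))
  expect_lt(mean(noisy$ref$weights), 1)
})

test_that("planted profiles correlate only at aligned columns", {
  tpl <- generate_structure(45, seed = 81)
  sp <- pair_spec(template_length = 45, seed = 82)
  q <- derive_query(tpl, sp)
  profs <- synthesize_profiles(tpl$record, q$record, q$ref, sp)
  expect_equal(rowSums(profs$profT), rep(1, nrow(profs$profT)))
  expect_equal(rowSums(profs$profQ), rep(1, nrow(profs$profQ)))
  expect_true(all(profs$profT >= 0))

  pr <- q$ref$pairs
  aligned <- mean(vapply(seq_len(nrow(pr)), function(r)
    sum(profs$profT[pr[r, 1], ] * profs$profQ[pr[r, 2], ]), numeric(1)))
  set.seed(83)
  rand <- mean(replicate(100, {
    i <- sample(nrow(profs$profT), 1); j <- sample(nrow(profs$profQ), 1)
    sum(profs$profT[i, ] * profs$profQ[j, ])
  }))
  expect_gt(aligned, rand)
})

test_that("datasets are reproducible and carry positive labels", {
  d1 <- generate_dataset(3, pair_spec(template_length = 20), seed = 84)
  d2 <- generate_dataset(3, pair_spec(template_length = 20), seed = 84)
  expect_identical(d1$samples[[2]]$x, d2$samples[[2]]$x)
  expect_identical(d1$samples[[3]]$w, d2$samples[[3]]$w)
  expect_length(d1$manifest, 3L)

  for (s in d1$samples) {
    expect_equal(dim(s$x)[3], 77L)
    expect_true(all(is.finite(s$x)))
    expect_gte(sum(s$w > 0), 1)
    # at most one positive per row and column
    expect_true(all(rowSums(s$w > 0) <= 1))
    expect_true(all(colSums(s$w > 0) <= 1))
  }
})

test_that("profile similarity alone recovers most reference pairs", {
  # learnability floor for the fixtures: the planted profile signal plus
  # MAC decoding should recover >= 70% of pairs before any training
  recalls <- vapply(c(21, 22, 23), function(sd) {
    sp <- pair_spec(coord_noise_sd = 0, indel_rate = 0.1, seed = sd)
    s <- generate_pair(sp)
    dotm <- s$profiles$profT %*% t(s$profiles$profQ)
    dotm <- (dotm - min(dotm)) / (max(dotm) - min(dotm) + 1e-12)
    al <- mac_align(dotm * 0.98 + 0.01, 0.3)
    pair_accuracy(al, s$ref)$recall
  }, numeric(1))
  expect_true(all(recalls >= 0.7))
})

test_that("synthetic pairs write to files every reader accepts", {
  s <- generate_pair(pair_spec(template_length = 25, seed = 85))
  dir <- file.path(tempdir(), "synthpair")
  files <- write_synthetic_pair(s, dir, "p1")
  expect_true(all(file.exists(files)))

  rec <- read_structure(file.path(dir, "p1_template.pdb"), "A")
  expect_equal(length(rec), length(s$template$record))
  expect_equal(rec$ca_coords, unname(s$template$record$ca_coords),
               tolerance = 1e-3)  # PDB has 3 decimals

  ref <- read_reference_tsv(file.path(dir, "p1_ref.tsv"))
  expect_equal(ref$pairs, s$ref$pairs)

  cm <- read_matrix(file.path(dir, "p1_query_contacts.txt"))
  expect_equal(nrow(cm), length(s$query$record))

  seqs <- read_fasta(file.path(dir, "p1.fasta"))
  expect_equal(seqs[[1]]$sequence, s$template$record$sequence)

  ann <- read_annotation(file.path(dir, "p1_query_ann.tsv"))
  expect_equal(nrow(ann), length(s$query$record))
})
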