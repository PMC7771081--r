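test_that("profile frequencies count non-gap symbols with pseudocounts", {
  msa <- protein_msa("q", c("A", "A", "A", "A", "A"))
  prof <- profile_from_msa(msa, pseudocount = 0)
  expect_equal(unname(prof[1, "A"]), 1)
  expect_equal(sum(prof[1, ]), 1)

  msa2 <- protein_msa("q", c("A", "A", "C", "-"))
  prof2 <- profile_from_msa(msa2, pseudocount = 0)
  expect_equal(unname(prof2[1, "A"]), 2 / 3)
  expect_equal(unname(prof2[1, "C"]), 1 / 3)

  # simplex invariant for any positive pseudocount
  set.seed(7)
  for (pc in c(1e-3, 0.1, 1)) {
    rows <- c("ACDV", "AC-V", "GCDV")
    prof3 <- profile_from_msa(protein_msa("q", rows), pc)
    expect_equal(rowSums(prof3), rep(1, 4))
    expect_true(all(prof3 >= 0))
  }
})

test_that("contact numbers exclude sequence neighbours and scale by 0.1", {
  one <- protein_record("p", "A", ca_coords = matrix(0, 1, 3),
                        cb_coords = matrix(0, 1, 3))
  expect_equal(contact_numbers(one), matrix(0, 1, 2))

  # three collinear residues spaced 3.8 A: only the 1-3 pair (7.6 A) is
  # both within 8 A and at sequence separation >= 2
  xyz <- cbind(c(0, 3.8, 7.6), 0, 0)
  three <- protein_record("p", "AAA", ca_coords = xyz, cb_coords = xyz)
  cn <- contact_numbers(three)
  expect_equal(cn[, 1], c(0.1, 0, 0.1))
  expect_equal(cn[, 2], c(0.1, 0, 0.1))
})

test_that("contact map thresholds strictly at 8 Angstrom", {
  mk <- function(d) {
    xyz <- rbind(c(0, 0, 0), c(d, 0, 0))
    protein_record("p", "AA", ca_coords = xyz, cb_coords = xyz)
  }
  expect_equal(contact_map_from_coords(mk(7.9))$m[1, 2], 1)
  expect_equal(contact_map_from_coords(mk(8.0))$m[1, 2], 0)

  set.seed(5)
  xyz <- matrix(rnorm(30, sd = 5), 10, 3)
  rec <- protein_record("p", strrep("A", 10), ca_coords = xyz,
                        cb_coords = xyz)
  cm <- contact_map_from_coords(rec)
  expect_true(isSymmetric(cm$m))
  expect_equal(diag(cm$m), rep(0, 10))
})

test_that("eigen embedding selects by |lambda| with positive tie-break", {
  z <- eigen_embedding(contact_map(matrix(0, 3, 3)), K = 2)
  expect_equal(z$lambdas, c(0, 0))

  path2 <- contact_map(matrix(c(0, 1, 1, 0), 2, 2))
  e <- eigen_embedding(path2, K = 1)
  expect_equal(e$lambdas, 1)  # +1 wins the tie against -1
  expect_equal(abs(e$vectors[1, ]), c(1, 1) / sqrt(2))

  path3 <- contact_map(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3))
  e3 <- eigen_embedding(path3, K = 1)
  expect_equal(e3$lambdas, sqrt(2))
  expect_equal(abs(e3$vectors[1, ]), c(0.5, sqrt(0.5), 0.5))

  # shorter protein than K: zero padding
  ep <- eigen_embedding(path2, K = 8)
  expect_equal(ep$lambdas[3:8], rep(0, 6))
  expect_equal(dim(ep$vectors), c(8L, 2L))
})

test_that("eigen pair features match the explicit-loop oracle", {
  path2 <- matrix(c(0, 1, 1, 0), 2, 2)
  f <- eigen_pair_features(eigen_embedding(contact_map(path2), 1),
                           eigen_embedding(contact_map(path2), 1))
  expect_equal(f[, , 1], matrix(0.5, 2, 2))

  set.seed(11)
  for (trial in 1:10) {
    LT <- sample(2:12, 1); LQ <- sample(2:12, 1)
    MT <- matrix(rnorm(LT^2), LT); MT <- (MT + t(MT)) / 2
    MQ <- matrix(rnorm(LQ^2), LQ); MQ <- (MQ + t(MQ)) / 2
    got <- eigen_pair_features(eigen_embedding(MT, 8),
                               eigen_embedding(MQ, 8))
    want <- eigen_pair_oracle(MT, MQ, 8)
    expect_lt(max(abs(got - want)), 1e-10)
    # template/query swap transposes every channel
    swapped <- eigen_pair_features(eigen_embedding(MQ, 8),
                                   eigen_embedding(MT, 8))
    for (k in 1:8) expect_equal(swapped[, , k], t(got[, , k]))
  }

  # zero contact matrix contributes all-zero channels
  f0 <- eigen_pair_features(eigen_embedding(matrix(0, 4, 4), 8),
                            eigen_embedding(contact_map(path2), 8))
  expect_equal(max(abs(f0)), 0)
})

test_that("eigen channels are symmetric when template equals query", {
  set.seed(12)
  M <- matrix(rnorm(49), 7); M <- (M + t(M)) / 2
  emb <- eigen_embedding(M, 8)
  f <- eigen_pair_features(emb, emb)
  for (k in 1:8) expect_equal(f[, , k], t(f[, , k]))
})

test_that("observed template features follow the 13-column encoding", {
  xyz <- cbind(c(0, 3.8, 7.6), 0, 0)
  rec <- protein_record("p", "AAA", ca_coords = xyz, cb_coords = xyz)
  ann <- annotation_table(data.frame(
    ss8 = c("H", "H", "H"), ss3 = c("H", "H", "H"),
    rsa = c(0.5, 0.2, 0.9),
    phi = c(NA, -60, -60), psi = c(-45, -45, NA),
    interface_prob = 0, disorder_prob = 0))
  f <- observed_template_features(rec, ann)
  expect_equal(ncol(f), 13L)
  expect_equal(f[2, 1:8], c(1, 0, 0, 0, 0, 0, 0, 0))  # one-hot H
  expect_equal(f[2, 9], 0.2)
  expect_equal(f[2, 10], -60 / 180)
  expect_equal(f[2, 11], -45 / 180)
  expect_equal(f[1, 10], 0)  # missing phi at the N-terminus
  expect_equal(f[3, 11], 0)  # missing psi at the C-terminus
  expect_error(observed_template_features(rec, ann[1:2, ]), "length")
})

test_that("predicted features follow the 8-column encoding", {
  ann <- annotation_table(data.frame(
    ss3 = "C", rsa = 1.0, phi = 30, psi = 60,
    interface_prob = 0, disorder_prob = 1))
  f <- predicted_features(ann)
  expect_equal(dim(f), c(1L, 8L))
  expect_equal(as.numeric(f),
               c(0, 0, 1, 1.0, 30 / 180, 60 / 180, 0, 1))
  expect_error(predicted_features(annotation_table(data.frame(ss3 = "C"))),
               "rsa")
  expect_error(annotation_table(data.frame(ss3 = "C", rsa = 1.7)),
               "\\[0, 1\\]")
})

test_that("pair tensor assembly fixes the 77-channel layout", {
  set.seed(21)
  profT <- matrix(1 / 20, 3, 20); profQ <- matrix(1 / 20, 2, 20)
  profT[, 1] <- seq(0.1, 0.3, length.out = 3)
  profQ[, 2] <- c(0.4, 0.6)
  obsT <- matrix(rnorm(3 * 13), 3, 13)
  predT <- matrix(rnorm(3 * 8), 3, 8)
  predQ <- matrix(rnorm(2 * 8), 2, 8)
  eig <- array(rnorm(3 * 2 * 8), c(3, 2, 8))
  x <- assemble_pair_tensor(profT, profQ, obsT, predT, predQ, eig)
  expect_equal(dim(x), c(3L, 2L, 77L))
  # template channels constant across query axis and vice versa
  expect_equal(x[2, 1, 1], x[2, 2, 1])
  expect_equal(x[1, 2, 21], x[3, 2, 21])
  expect_equal(x[1, 1, 1], profT[1, 1])
  expect_equal(x[1, 1, 21], profQ[1, 1])
  expect_equal(x[2, 2, 70:77], eig[2, 2, ])
  expect_error(assemble_pair_tensor(profT, profQ, obsT[1:2, ], predT,
                                    predQ, eig), "observed")
})

test_that("pair tensors round-trip through the binary container", {
  set.seed(31)
  x <- assemble_pair_tensor(matrix(1 / 20, 4, 20), matrix(1 / 20, 3, 20),
                            matrix(rnorm(52), 4, 13),
                            matrix(rnorm(32), 4, 8),
                            matrix(rnorm(24), 3, 8),
                            array(rnorm(96), c(4, 3, 8)))
  path <- tempfile()
  write_pair_tensor(x, path)
  y <- read_pair_tensor(path)
  expect_equal(unclass(y)[seq_along(y)], unclass(x)[seq_along(x)])
  expect_equal(dim(y), dim(x))
})
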