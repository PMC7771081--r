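test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(41)
  X <- matrix(rnorm(30, sd = 6), 10, 3)

  self <- kabsch_superpose(X, X)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-8)

  Y <- sweep(X, 2, c(5, 0, 0), "+")
  shifted <- kabsch_superpose(X, Y)
  expect_equal(shifted$rmsd, 0, tolerance = 1e-10)
  # the recovered translation maps Y back onto X
  expect_equal(shifted$translation, c(-5, 0, 0), tolerance = 1e-8)
  expect_equal(apply_superposition(shifted, Y), X, tolerance = 1e-8)

  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- kabsch_superpose(X, X %*% t(Rz))
  expect_equal(rot$rmsd, 0, tolerance = 1e-10)
  expect_equal(rot$rotation %*% Rz, diag(3), tolerance = 1e-8)
  expect_equal(det(rot$rotation), 1, tolerance = 1e-8)

  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "n >= 3")
})

test_that("Kabsch rmsd is invariant under common rigid motions", {
  set.seed(42)
  X <- matrix(rnorm(24, sd = 4), 8, 3)
  Y <- X + matrix(rnorm(24, sd = 1), 8, 3)
  base <- kabsch_superpose(X, Y)$rmsd
  for (trial in 1:5) {
    th <- runif(1, 0, 2 * pi)
    sh <- rnorm(3, sd = 20)
    moved <- kabsch_superpose(rigid_motion(X, th, sh),
                              rigid_motion(Y, th, sh))$rmsd
    expect_equal(moved, base, tolerance = 1e-8)
  }
})

test_that("d0 follows the TM-score convention with a 0.5 A floor", {
  expect_equal(d0(15), 0.5)
  expect_equal(d0(21), 0.5)  # 1.24 * 6^(1/3) - 1.8 < 0.5
  expect_equal(d0(100), 1.24 * 85^(1 / 3) - 1.8)
  L <- 1:300
  expect_true(all(diff(d0(L)) >= 0))
})

test_that("local TM-score weights hit the formula's anchor points", {
  set.seed(43)
  X <- matrix(rnorm(30, sd = 8), 10, 3)
  ref <- reference_alignment(cbind(1:10, 1:10))

  # exact copy: every aligned pair at distance 0, weight 1
  w1 <- local_tm_weights(ref, X, rigid_motion(X))
  expect_equal(w1$weights, rep(1, 10))

  # symmetric cross with balanced +/- z displacements: the optimal
  # superposition is the identity, so every pair sits at exactly d
  a <- 10
  caT <- rbind(c(a, 0, 0), c(-a, 0, 0), c(0, a, 0), c(0, -a, 0))
  d <- d0(4)  # local_tm_weights normalizes by the mean length, here 4
  caQ <- caT + rbind(c(0, 0, d), c(0, 0, d), c(0, 0, -d), c(0, 0, -d))
  w2 <- local_tm_weights(reference_alignment(cbind(1:4, 1:4)), caT, caQ)
  expect_equal(w2$weights, rep(0.5, 4))

  # weights always in [0, 1]
  for (trial in 1:5) {
    Y <- X + matrix(rnorm(30, sd = 3), 10, 3)
    w <- local_tm_weights(ref, X, Y)$weights
    expect_true(all(w >= 0 & w <= 1))
  }
  expect_error(local_tm_weights(reference_alignment(cbind(1:2, 1:2)),
                                X, X), ">= 3")
})

test_that("TM-score and GDT are 1 for self and rigid copies", {
  set.seed(44)
  g <- generate_structure(40, seed = 44)
  X <- g$record$ca_coords
  idp <- cbind(1:40, 1:40)
  expect_equal(tm_score(idp, X, X, 40), 1)
  expect_equal(gdt(idp, X, X, 40), 1)
  moved <- rigid_motion(X, 1.2, c(100, 0, 0))
  expect_equal(tm_score(idp, X, moved, 40), 1, tolerance = 1e-9)
  expect_equal(gdt(idp, X, moved, 40), 1, tolerance = 1e-9)
})

test_that("TM-score and GDT are invariant under rigid motion of the model", {
  set.seed(45)
  g <- generate_structure(35, seed = 45)
  X <- g$record$ca_coords
  Y <- X + matrix(rnorm(105, sd = 2), 35, 3)
  idp <- cbind(1:35, 1:35)
  tm0 <- tm_score(idp, X, Y, 35)
  gdt0 <- gdt(idp, X, Y, 35)
  Ym <- rigid_motion(Y, 0.9, c(-30, 12, 4))
  expect_equal(tm_score(idp, X, Ym, 35), tm0, tolerance = 1e-8)
  expect_equal(gdt(idp, X, Ym, 35), gdt0, tolerance = 1e-8)
  expect_true(tm0 > 0 && tm0 <= 1)
  expect_true(gdt0 >= 0 && gdt0 <= 1)
})

test_that("TM-score never falls below the all-pair Kabsch lower bound", {
  set.seed(46)
  for (trial in 1:5) {
    g <- generate_structure(30, seed = 460 + trial)
    X <- g$record$ca_coords
    Y <- X + matrix(rnorm(90, sd = trial), 30, 3)
    sp <- kabsch_superpose(X, Y)
    d <- sqrt(rowSums((X - apply_superposition(sp, Y))^2))
    lower <- sum(1 / (1 + (d / d0(30))^2)) / 30
    expect_gte(tm_score(cbind(1:30, 1:30), X, Y, 30) + 1e-12, lower)
  }
})

test_that("pair accuracy handles exact, disjoint and partial predictions", {
  ref <- reference_alignment(cbind(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 4L)))
  same <- list(pairs = ref$pairs)
  expect_equal(pair_accuracy(same, ref),
               list(precision = 1, recall = 1, f1 = 1))

  disjoint <- list(pairs = cbind(c(1L, 2L), c(2L, 3L)))
  acc <- pair_accuracy(disjoint, ref)
  expect_equal(acc$precision, 0)
  expect_equal(acc$recall, 0)
  expect_equal(acc$f1, 0)

  half <- list(pairs = ref$pairs[1:2, , drop = FALSE])
  acc2 <- pair_accuracy(half, ref)
  expect_equal(acc2$precision, 1)
  expect_equal(acc2$recall, 0.5)

  none <- list(pairs = cbind(integer(0), integer(0)))
  expect_equal(pair_accuracy(none, ref)$precision, 0)
  empty_ref <- reference_alignment(cbind(integer(0), integer(0)))
  expect_equal(pair_accuracy(none, empty_ref)$precision, 1)
})
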