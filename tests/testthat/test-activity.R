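test_that("normalize_expression median-centers one-channel data only", {
  m1 <- expression_matrix(
    matrix(c(1, 2, 3), 1, dimnames = list("G1", c("a", "b", "c"))),
    "one_channel")
  expect_equal(unname(normalize_expression(m1)[1, ]), c(-1, 0, 1))

  m2 <- expression_matrix(
    matrix(c(1, 2, 3, 10), 1, dimnames = list("G1", letters[1:4])),
    "one_channel")
  # even sample count: median is the mean of the middle pair (2.5)
  expect_equal(unname(normalize_expression(m2)[1, ]),
               c(-1.5, -0.5, 0.5, 7.5))

  m3 <- expression_matrix(
    matrix(c(0.5, -0.2), 1, dimnames = list("G1", c("a", "b"))),
    "two_channel")
  expect_equal(unname(normalize_expression(m3)[1, ]), c(0.5, -0.2))
  expect_identical(attr(normalize_expression(m3), "channel_mode"),
                   "pre_normalized")
})

test_that("weight vectors flag targets, drop absent symbols, and reject
           degenerate target/background splits", {
  m <- random_matrix(4, 3, seed = 1)
  rownames(m) <- c("A", "B", "C", "D")
  wv <- make_weight_vector(gene_set("R", c("A", "C")), m)
  expect_identical(unname(wv$values), c(1L, 0L, 1L, 0L))
  expect_identical(wv$n_targets_effective, 2L)

  expect_warning(wv <- make_weight_vector(gene_set("R", c("A", "X")), m),
                 "X")
  expect_identical(unname(wv$values), c(1L, 0L, 0L, 0L))

  expect_error(
    suppressWarnings(make_weight_vector(gene_set("R", c("X", "Y")), m)),
    "no members")
  expect_error(make_weight_vector(gene_set("R", c("A", "B", "C", "D")), m),
               "background")
})

test_that("running-sum curves match the hand-computed worked example", {
  ex <- worked_example()
  cp <- sample_curves(ex$weights, ex$e)
  expect_equal(cp$foreground, c(0.6, 1, 1, 1, 1, 1), tolerance = 1e-15)
  expect_equal(cp$background, c(0, 0, 1 / 7, 2 / 7, 4 / 7, 1),
               tolerance = 1e-15)
  expect_equal(cp$foreground - cp$background, ex$d_expected,
               tolerance = 1e-15)
  expect_equal(preliminary_score(cp), 1)

  # mirror instance: targets hold the two most-negative values
  cp_neg <- sample_curves(rev(ex$weights), ex$e)
  expect_equal(preliminary_score(cp_neg), -1)

  # single target with the top expression jumps F to 1 at rank 1
  cp1 <- sample_curves(c(1L, 0L, 0L, 0L), c(5, 1, 0.5, -2))
  expect_equal(cp1$foreground[1L], 1)
})

test_that("ties sort by gene index and zero-mass classes fall back to
           uniform increments", {
  e <- rep(2, 5)
  cp <- sample_curves(c(0L, 1L, 0L, 1L, 0L), e)
  expect_identical(cp$order, 1:5)
  expect_equal(diff(c(0, cp$foreground[c(2, 4)])), c(0.5, 0.5))
  expect_equal(diff(c(0, cp$background[c(1, 3, 5)])), rep(1 / 3, 3))

  # all-zero target expression: foreground steps 1/count at target ranks
  cp0 <- sample_curves(c(1L, 1L, 0L, 0L), c(0, 0, 3, -1))
  expect_equal(cp0$foreground, c(0, 0.5, 1, 1))
})

test_that("preliminary_score equals a brute-force deviation scan", {
  set.seed(21)
  for (i in 1:50) {
    e <- rnorm(10)
    k <- sample(1:9, 1)
    targets <- sample(10, k)
    w <- integer(10)
    w[targets] <- 1L
    for (mode in c("absolute", "uniform")) {
      oracle <- brute_curve_score(e, targets, mode)
      cp <- sample_curves(w, e, weighting = mode)
      expect_equal(cp$foreground - cp$background, oracle$d,
                   tolerance = 1e-12)
      expect_equal(preliminary_score(cp), oracle$score, tolerance = 1e-12)
    }
  }
})

test_that("curves are non-decreasing and terminate at one", {
  m <- random_matrix(60, 8, seed = 5)
  set.seed(9)
  w <- integer(60)
  w[sample(60, 12)] <- 1L
  for (j in seq_len(ncol(m))) {
    cp <- sample_curves(w, m[, j])
    expect_true(all(diff(cp$foreground) >= -1e-12))
    expect_true(all(diff(cp$background) >= -1e-12))
    expect_equal(cp$foreground[60], 1, tolerance = 1e-12)
    expect_equal(cp$background[60], 1, tolerance = 1e-12)
  }
})

test_that("negating a tie-free column negates the preliminary score", {
  set.seed(31)
  w <- integer(30)
  w[sample(30, 8)] <- 1L
  for (i in 1:25) {
    e <- rnorm(30)
    s_pos <- preliminary_score(sample_curves(w, e))
    s_neg <- preliminary_score(sample_curves(w, -e))
    expect_equal(s_neg, -s_pos, tolerance = 1e-12)
  }
})

test_that("the compiled kernel agrees with the reference R path", {
  m <- random_matrix(40, 6, seed = 17)
  set.seed(18)
  memb <- sapply(1:15, function(i) {
    v <- integer(40)
    v[sample(40, sample(2:20, 1))] <- 1L
    v
  })
  fast <- ictair:::base_scores_cpp(unclass(m), memb, TRUE)
  slow <- sapply(seq_len(ncol(m)), function(j) {
    apply(memb, 2, function(w) preliminary_score(sample_curves(w, m[, j])))
  })
  expect_equal(fast, slow, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("iRAS is the preliminary score over the permutation-null mean and
           is deterministic per seed", {
  m <- random_matrix(50, 4, seed = 7)
  s <- gene_set("R", rownames(m)[c(3, 9, 20, 31, 44)])
  p1 <- compute_iras(s, m, n_permutations = 50, seed = 123)
  p2 <- compute_iras(s, m, n_permutations = 50, seed = 123)
  expect_identical(p1$scores, p2$scores)
  expect_equal(p1$scores, p1$preliminary / p1$null_mean_abs)
  expect_true(all(p1$null_mean_abs > 0))
  p3 <- compute_iras(s, m, n_permutations = 50, seed = 124)
  expect_false(identical(p1$scores, p3$scores))
})

test_that("iRAS sign follows where the targets sit in the expression
           ranking", {
  set.seed(41)
  vals <- matrix(rnorm(60 * 2, sd = 0.1), 60,
                 dimnames = list(sprintf("G%02d", 1:60), c("up", "down")))
  targets <- sprintf("G%02d", 1:8)
  vals[targets, "up"] <- 5 + abs(rnorm(8))     # targets top-ranked
  vals[targets, "down"] <- -5 - abs(rnorm(8))  # targets bottom-ranked
  m <- expression_matrix(vals, "pre_normalized")
  prof <- compute_iras(gene_set("R", targets), m, 100, seed = 1)
  expect_gt(prof$scores[["up"]], 0)
  expect_lt(prof$scores[["down"]], 0)
})

test_that("permuting sample columns permutes the scores identically", {
  m <- random_matrix(40, 6, seed = 19)
  s <- gene_set("R", rownames(m)[1:7])
  perm <- c(4, 1, 6, 2, 5, 3)
  mp <- expression_matrix(unclass(m)[, perm], "pre_normalized")
  a <- compute_iras(s, m, 60, seed = 5)$scores
  b <- compute_iras(s, mp, 60, seed = 5)$scores
  expect_identical(unname(b), unname(a[perm]))
})

test_that("compute_iras validates its inputs", {
  m <- random_matrix(20, 3, seed = 2)
  s <- gene_set("R", rownames(m)[1:4])
  expect_error(compute_iras(s, m, n_permutations = 0, seed = 1), "positive")
  raw <- expression_matrix(unclass(m), "one_channel")
  expect_error(compute_iras(s, raw, 10, seed = 1), "normalize")
})

test_that("score_collection is order-independent per set and isolates
           failures", {
  m <- random_matrix(50, 5, seed = 23)
  sets <- list(gene_set("A", rownames(m)[1:6]),
               gene_set("B", rownames(m)[10:18]),
               gene_set("BAD", c("NOPE1", "NOPE2")))
  am <- suppressWarnings(score_collection(sets, m, 40, seed = 9))
  expect_identical(rownames(am), c("A", "B"))
  expect_named(attr(am, "errors"), "BAD")
  solo <- suppressWarnings(score_collection(sets[2], m, 40, seed = 9))
  expect_identical(am["B", ], solo["B", ])
})
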