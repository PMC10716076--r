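test_that("noiseless allometric signal gives r2 = 1 and the minimal p", {
  set.seed(81)
  n <- 20; p <- 12
  v <- rnorm(p)
  lncs <- rnorm(n)
  tangent <- outer(rep(1, n), rnorm(p)) + outer(lncs, v)
  res <- shape_size_regression(tangent, lncs, n_perm = 199, seed = 9)
  expect_equal(res$r2, 1, tolerance = 1e-9)
  expect_equal(res$p_perm, 1 / 200)
  expect_equal(res$pct_explained, 100, tolerance = 1e-6)
  expect_error(shape_size_regression(tangent, rep(1, n), n_perm = 9, seed = 1),
               "constant")
})

test_that("size regression holds its type-I error rate under the null", {
  # 200 seeded replicates, n = 30, 1000 permutations each
  set.seed(82)
  n <- 30; p <- 10
  rejections <- vapply(1:200, function(b) {
    tangent <- matrix(rnorm(n * p), n)
    x <- rnorm(n)
    shape_size_regression(tangent, x, n_perm = 1000, seed = b)$p_perm < 0.05
  }, TRUE)
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.08)
})

test_that("regression statistics are invariant to joint specimen relabelling", {
  set.seed(83)
  tangent <- matrix(rnorm(25 * 8), 25)
  x <- rnorm(25)
  r1 <- shape_size_regression(tangent, x, n_perm = 49, seed = 3)
  perm <- sample.int(25)
  r2 <- shape_size_regression(tangent[perm, ], x[perm], n_perm = 49, seed = 3)
  expect_equal(r2$F, r1$F, tolerance = 1e-12)
  expect_equal(r2$r2, r1$r2, tolerance = 1e-12)
})

test_that("group ANOVA: saturated power, small-group errors, type-I control", {
  set.seed(84)
  og <- offset_groups(n_per = 10, delta = 1, noise = 0.01)
  res <- procrustes_anova(og$tangent, og$labels, n_perm = 199, seed = 2)
  expect_equal(res$p_perm, 1 / 200)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 18L)

  expect_error(procrustes_anova(og$tangent, c("A", rep("B", 19)),
                                n_perm = 9, seed = 1), "A")

  rejections <- vapply(1:200, function(b) {
    Y <- matrix(rnorm(20 * 6), 20)
    procrustes_anova(Y, rep(c("A", "B"), each = 10), n_perm = 999,
                     seed = b)$p_perm < 0.05
  }, TRUE)
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.08)
})

test_that("permutation scheme is self-consistent: p uniform under relabelling", {
  set.seed(85)
  Y <- matrix(rnorm(24 * 6), 24)
  labs <- rep(c("A", "B"), each = 12)
  ps <- vapply(1:200, function(b) {
    procrustes_anova(Y, sample(labs), n_perm = 199, seed = b)$p_perm
  }, 1.0)
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_gt(min(ps), 0)
  expect_lte(max(ps), 1)
})

test_that("group tests are invariant under global rotation of the shape data", {
  set.seed(86)
  tp <- make_template_skull(builtin_landmark_set("neurocranial"))
  cfgs <- lapply(1:12, function(i) tp + matrix(rnorm(27, 0, 2), 9))
  g <- gpa(cfgs)
  labs <- rep(c("A", "B"), each = 6)
  R <- rand_rotation()
  rot_aligned <- array(NA_real_, dim(g$aligned))
  for (i in 1:12) rot_aligned[, , i] <- g$aligned[, , i] %*% R
  g2 <- g
  g2$aligned <- rot_aligned
  g2$consensus <- g$consensus %*% R
  g2$tangent <- tangent_projection(g2)
  a1 <- procrustes_anova(g$tangent, labs, n_perm = 49, seed = 4)
  a2 <- procrustes_anova(g2$tangent, labs, n_perm = 49, seed = 4)
  expect_equal(a2$F, a1$F, tolerance = 1e-12)
  p1 <- pairwise_shape_distances(g$tangent, labs, g$consensus, 49, seed = 4)
  p2 <- pairwise_shape_distances(g2$tangent, labs, g2$consensus, 49, seed = 4)
  expect_equal(p2$distance, p1$distance, tolerance = 1e-12)
})

test_that("PCA of tangent data: eigenvalue/score identities and rank bound", {
  set.seed(87)
  Y <- matrix(rnorm(15 * 40), 15)
  pc <- shape_pca(Y)
  expect_equal(apply(pc$scores, 2, stats::var), unname(pc$eigenvalues),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sum(pc$eigenvalues), sum(scale(Y, scale = FALSE)^2) / 14,
               tolerance = 1e-9)
  expect_lte(ncol(pc$scores), min(nrow(Y) - 1, ncol(Y)))
  expect_lt(max(abs(colMeans(pc$scores))), 1e-10)
})

test_that("CVA: axis count, collinear means, and label-shuffle degradation", {
  set.seed(88)
  og <- offset_groups(n_per = 10, delta = 0.3, noise = 0.05)
  two <- cva(og$tangent, og$labels)
  expect_equal(two$n_axes, 1L)
  expect_equal(sum(two$pct_differentiation), 100, tolerance = 1e-6)

  # three groups with exactly collinear means: the second axis carries
  # no between-group variance
  n_per <- 12; p <- 10
  dirv <- c(1, rep(0, p - 1))
  Y <- do.call(rbind, lapply(c(-0.4, 0, 0.4), function(d) {
    G <- matrix(rnorm(n_per * p, 0, 0.05), n_per)
    sweep(G, 2, colMeans(G)) + matrix(d * dirv, n_per, p, byrow = TRUE)
  }))
  labs3 <- rep(c("A", "B", "C"), each = n_per)
  res3 <- cva(Y, labs3)
  expect_equal(res3$n_axes, 2L)
  expect_equal(res3$pct_differentiation[1], 100, tolerance = 1e-6)
  expect_lt(res3$pct_differentiation[2], 1e-6)

  # shuffling labels destroys CV1 separation in nearly all replicates
  worse <- vapply(1:100, function(b) {
    set.seed(1000 + b)
    cva(Y, sample(labs3))$eigenvalues[1] < res3$eigenvalues[1]
  }, TRUE)
  expect_gte(mean(worse), 0.95)
})

test_that("pairwise distance table: duplicate groups, symmetry, recovery", {
  set.seed(89)
  tp <- make_template_skull(builtin_landmark_set("neurocranial"))
  cfgs <- lapply(1:8, function(i) tp + matrix(rnorm(27, 0, 2), 9))
  g <- gpa(cfgs)
  # the same 8 specimens labelled twice: zero distance, p ~ 1
  dup <- pairwise_shape_distances(rbind(g$tangent, g$tangent),
                                  rep(c("A", "B"), each = 8), g$consensus,
                                  n_perm = 99, seed = 7)
  expect_lt(dup$distance["A", "B"], 1e-9)
  expect_gt(dup$p_perm["A", "B"], 0.9)
  expect_identical(dup$distance, t(dup$distance))
  expect_equal(diag(dup$distance), c(A = 0, B = 0))
  # single-member groups get a distance but a flagged p
  single <- pairwise_shape_distances(g$tangent,
                                     c(rep("A", 7), "B"), g$consensus,
                                     n_perm = 49, seed = 7)
  expect_true(is.finite(single$distance["A", "B"]))
  expect_true(is.na(single$p_perm["A", "B"]))
})

test_that("permutation results are reproducible under a fixed seed", {
  set.seed(90)
  og <- offset_groups()
  a <- procrustes_anova(og$tangent, og$labels, n_perm = 99, seed = 123)
  b <- procrustes_anova(og$tangent, og$labels, n_perm = 99, seed = 123)
  expect_identical(a, b)
  x <- rnorm(30)
  r1 <- shape_size_regression(og$tangent, x, n_perm = 99, seed = 5)
  r2 <- shape_size_regression(og$tangent, x, n_perm = 99, seed = 5)
  expect_identical(r1, r2)
})
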