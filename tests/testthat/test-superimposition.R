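test_that("centroid size: closed form, homogeneity, translation invariance", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(centroid_size(cube), sqrt(6), tolerance = 1e-12)
  set.seed(61)
  x <- matrix(rnorm(24), 8)
  for (k in c(0.5, 2, 10))
    expect_equal(centroid_size(k * x), k * centroid_size(x), tolerance = 1e-12)
  expect_equal(centroid_size(sweep(x, 2, c(13, -7, 2), `+`)),
               centroid_size(x), tolerance = 1e-9)
  expect_error(centroid_size(matrix(1, 4, 3)), "coincident")
})

test_that("ordinary Procrustes alignment recovers exact similarity transforms", {
  set.seed(62)
  a <- matrix(rnorm(24), 8)
  R <- rotation_about(rnorm(3), 37 * pi / 180)
  b <- sweep(1 / 1.7 * a %*% R, 2, c(4, -2, 9), `+`)  # a = 1.7 * inv-transform
  fit <- procrustes_align(a, b)
  expect_lt(fit$residual, 1e-9)
  expect_equal(fit$scale, 1.7, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
  expect_lt(max(abs(fit$fitted - a)), 1e-8)
})

test_that("reflections are never used: chiral mirror images keep residual > 0", {
  set.seed(63)
  a <- matrix(rnorm(18), 6)  # random 3D hexad is chiral a.s.
  b <- a %*% diag(c(-1, 1, 1))
  fit <- procrustes_align(a, b)
  expect_gt(fit$residual, 1e-3)
})

test_that("alignment residual matches brute-force and vegan oracles", {
  set.seed(64)
  a <- matrix(rnorm(18), 6)
  b <- matrix(rnorm(18), 6)
  fit <- procrustes_align(a, b, allow_scale = TRUE)
  # brute force over a 4-degree Euler-angle grid, scale profiled out:
  # residual^2 = ||a_c||^2 - tr(R' M)^2 / ||b_c||^2, tr(R' M) = sum(R * M)
  ac <- scale(a, scale = FALSE); bc <- scale(b, scale = FALSE)
  M <- crossprod(bc, ac)
  # grid the first two Euler angles at 2 degrees; the trace is sinusoidal in
  # the final z-rotation, so its maximum over that angle is taken exactly
  step <- 2 * pi / 180
  best <- -Inf
  for (ph in seq(0, 2 * pi - step / 2, step)) {
    Rz1 <- rotation_about(c(0, 0, 1), ph)
    for (th in seq(0, pi, step)) {
      Rzy <- rotation_about(c(0, 1, 0), th) %*% Rz1
      M2 <- M %*% t(Rzy)
      tr <- sqrt((M2[1, 1] + M2[2, 2])^2 + (M2[2, 1] - M2[1, 2])^2) + M2[3, 3]
      if (tr > best) best <- tr
    }
  }
  res_grid <- sqrt(sum(ac^2) - best^2 / sum(bc^2))
  expect_lte(fit$residual, res_grid + 1e-9)       # ours is the true minimum
  expect_lt(res_grid - fit$residual, 0.02 * sqrt(sum(ac^2)))  # grid resolution
  skip_if_not_installed("vegan")
  vp <- vegan::procrustes(a, b, scale = TRUE, symmetric = FALSE)
  if (det(vp$rotation) > 0)  # vegan may pick a reflection; compare when proper
    expect_equal(fit$residual^2, sum(vp$ss), tolerance = 1e-8)
})

test_that("GPA collapses an orbit of one shape and centres the consensus", {
  set.seed(65)
  tp <- make_template_skull(builtin_landmark_set("neurocranial"))
  cfgs <- lapply(1:5, function(i)
    sweep(runif(1, 0.3, 3) * tp %*% rand_rotation(), 2, rnorm(3, 0, 50), `+`))
  g <- gpa(cfgs)
  for (i in 2:5)
    expect_lt(max(abs(g$aligned[, , i] - g$aligned[, , 1])), 1e-8)
  expect_lt(procrustes_distance(g$consensus, tp), 1e-8)
  expect_lt(max(abs(colMeans(g$consensus))), 1e-9)
  expect_equal(sqrt(sum(g$consensus^2)), 1, tolerance = 1e-9)
  expect_true(all(abs(apply(g$aligned, 3, function(x) sqrt(sum(x^2))) - 1) < 1e-9))
})

test_that("two-configuration consensus is Procrustes-equidistant from both", {
  set.seed(66)
  a <- matrix(rnorm(30), 10)
  b <- matrix(rnorm(30), 10)
  g <- gpa(list(a, b))
  expect_equal(procrustes_distance(g$consensus, a),
               procrustes_distance(g$consensus, b), tolerance = 1e-9)
})

test_that("GPA consensus is a consistent estimator of the template shape", {
  set.seed(67)
  tp <- preshape(make_template_skull(builtin_landmark_set("neurocranial")))
  n <- 20; sd_ <- 0.01
  cfgs <- lapply(1:n, function(i) tp + matrix(rnorm(27, 0, sd_), 9))
  g <- gpa(cfgs)
  fit <- procrustes_align(tp, g$consensus)  # remove arbitrary orientation
  expect_lt(max(abs(fit$fitted - tp)), 3 * sd_ / sqrt(n))
})

test_that("tangent projection: zero at consensus, idempotent, small-angle match", {
  set.seed(68)
  tp <- make_template_skull(builtin_landmark_set("neurocranial"))
  cfgs <- lapply(1:8, function(i) tp + matrix(rnorm(27, 0, 2), 9))
  g <- gpa(cfgs)
  cvec <- as.vector(g$consensus)
  expect_lt(max(abs(cvec - sum(cvec * cvec) * cvec)), 1e-12)  # consensus -> 0
  tg2 <- g$tangent - (g$tangent %*% cvec) %*% t(cvec)        # idempotence
  expect_lt(max(abs(tg2 - g$tangent)), 1e-12)
  mean(vapply(seq_len(8), function(i) {
    pd <- procrustes_distance(g$aligned[, , i], g$consensus)
    td <- sqrt(sum(g$tangent[i, ]^2))
    expect_lt(pd, 0.1)
    expect_lt(abs(td - pd) / pd, 0.01)
    pd
  }, 1.0))
  # tangent vectors average to (approximately) zero at the consensus
  expect_lt(max(abs(colSums(g$tangent))), 1e-8 * nrow(g$tangent))
})

test_that("Procrustes distance is a similarity-invariant shape metric", {
  set.seed(69)
  a <- matrix(rnorm(30), 10)
  b <- matrix(rnorm(30), 10)
  expect_lt(procrustes_distance(a, a), 1e-12)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
               tolerance = 1e-12)
  d0 <- procrustes_distance(a, b)
  for (i in 1:5) {
    a2 <- sweep(runif(1, 0.2, 5) * a %*% rand_rotation(), 2, rnorm(3, 0, 10), `+`)
    b2 <- sweep(runif(1, 0.2, 5) * b %*% rand_rotation(), 2, rnorm(3, 0, 10), `+`)
    expect_lt(abs(procrustes_distance(a2, b2) - d0), 1e-9)
  }
})

test_that("GPA output does not depend on input ordering", {
  set.seed(70)
  tp <- make_template_skull(builtin_landmark_set("neurocranial"))
  cfgs <- lapply(1:6, function(i) tp + matrix(rnorm(27, 0, 3), 9))
  g1 <- gpa(cfgs)
  perm <- c(4, 2, 6, 1, 5, 3)
  g2 <- gpa(cfgs[perm])
  expect_lt(procrustes_distance(g1$consensus, g2$consensus), 1e-9)
  d1 <- vapply(1:6, function(i) procrustes_distance(g1$aligned[, , i],
                                                    g1$consensus), 1.0)
  d2 <- vapply(1:6, function(i) procrustes_distance(g2$aligned[, , i],
                                                    g2$consensus), 1.0)
  expect_equal(d2, d1[perm], tolerance = 1e-9)
})
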