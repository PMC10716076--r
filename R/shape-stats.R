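#' Multivariate regression of shape on log centroid size
#'
#' Regresses tangent-space shape coordinates on a scalar size proxy
#' (natural log of centroid size) and summarises the fit Goodall-style over
#' all shape variables: r2 = SS_model / SS_total, F = (SS_model / 1) /
#' (SS_residual / (n - 2)). Significance is assessed by permuting the
#' predictor values against the shape rows.
#'
#' @param tangent n x p matrix of tangent coordinates.
#' @param ln_csize length-n numeric predictor (log centroid size).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed; the permutation-generation order is fixed
#'   (successive calls to `sample.int` after seeding).
#' @return object of class `shape_regression`: `F`, `r2`, `pct_explained`,
#'   `p_perm`, `df`, `n_perm`, `seed`, `coef` (p-vector of slopes).
#' @export
shape_size_regression <- function(tangent, ln_csize, n_perm = 10000, seed = 1) {
  tangent <- as.matrix(tangent)
  n <- nrow(tangent)
  if (length(ln_csize) != n) stop("predictor length mismatch", call. = FALSE)
  if (n < 3) stop("need at least 3 specimens", call. = FALSE)
  if (stats::sd(ln_csize) == 0)
    stop("constant predictor: no size variation", call. = FALSE)
  Y <- sweep(tangent, 2, colMeans(tangent))
  ss_total <- sum(Y^2)
  xc <- ln_csize - mean(ln_csize)
  sxx <- sum(xc^2)
  # single predictor: SS_model = || t(Y) x ||^2 / (x'x)
  ss_model_of <- function(x) sum(crossprod(Y, x)^2) / sum(x^2)
  f_of <- function(ssm) {
    ssr <- max(ss_total - ssm, 0)  # clamp: exact fits can go negative in fp
    if (ssr == 0) Inf else (ssm / 1) / (ssr / (n - 2))
  }
  ss_model <- ss_model_of(xc)
  Fobs <- f_of(ss_model)
  null_F <- with_seed(seed, vapply(seq_len(n_perm), function(b)
    f_of(ss_model_of(xc[sample.int(n)])), 1.0))
  r2 <- ss_model / ss_total
  structure(list(F = Fobs, r2 = r2, pct_explained = 100 * r2,
                 p_perm = perm_pvalue(null_F, Fobs), df = c(1L, n - 2L),
                 n_perm = n_perm, seed = seed,
                 coef = as.vector(crossprod(Y, xc)) / sxx),
            class = "shape_regression")
}

#' @export
print.shape_regression <- function(x, ...) {
  cat(sprintf("Shape ~ ln(CS): F(%d, %d) = %.3f, r2 = %.4f (%.2f%%), p = %.4g (%d perms)\n",
              x$df[1], x$df[2], x$F, x$r2, x$pct_explained, x$p_perm, x$n_perm))
  invisible(x)
}

goodall_f <- function(tangent, labels) {
  labels <- factor(labels)
  g <- nlevels(labels)
  n <- nrow(tangent)
  grand <- colMeans(tangent)
  ssb <- 0; ssw <- 0
  for (lv in levels(labels)) {
    Yg <- tangent[labels == lv, , drop = FALSE]
    mg <- colMeans(Yg)
    ssb <- ssb + nrow(Yg) * sum((mg - grand)^2)
    ssw <- ssw + sum(sweep(Yg, 2, mg)^2)
  }
  Fv <- (ssb / (g - 1)) / (ssw / (n - g))
  list(F = Fv, ssb = ssb, ssw = ssw, df = c(g - 1L, n - g))
}

#' Permutation MANOVA (Goodall-type F) on tangent coordinates
#'
#' Tests for shape differences among groups with the ratio of
#' between-group to within-group summed squared tangent deviations
#' (Goodall-type F, all shape variables pooled); significance comes from
#' permuting group labels. This permutation procedure is used where
#' classical parametric MANOVA would be singular (n << p for landmark
#' data); outputs are labelled "permutation MANOVA".
#'
#' @inheritParams shape_size_regression
#' @param labels group factor (each group needs >= 2 members).
#' @return object of class `shape_group_test`: `F`, `df_between`,
#'   `df_within`, `p_perm`, `n_perm`, `seed`.
#' @export
procrustes_anova <- function(tangent, labels, n_perm = 10000, seed = 1) {
  tangent <- as.matrix(tangent)
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(labels)
  if (any(sizes < 2))
    stop("group(s) with fewer than 2 members: ",
         paste(names(sizes)[sizes < 2], collapse = ", "),
         "; drop or merge before testing", call. = FALSE)
  obs <- goodall_f(tangent, labels)
  n <- nrow(tangent)
  null_F <- with_seed(seed, vapply(seq_len(n_perm), function(b)
    goodall_f(tangent, labels[sample.int(n)])$F, 1.0))
  structure(list(F = obs$F, df_between = obs$df[1], df_within = obs$df[2],
                 p_perm = perm_pvalue(null_F, obs$F), n_perm = n_perm,
                 seed = seed),
            class = "shape_group_test")
}

#' @export
print.shape_group_test <- function(x, ...) {
  cat(sprintf("Permutation MANOVA: F(%d, %d) = %.3f, p = %.4g (%d perms)\n",
              x$df_between, x$df_within, x$F, x$p_perm, x$n_perm))
  invisible(x)
}

#' Principal component analysis of tangent coordinates
#'
#' Eigen-decomposition of the tangent covariance matrix; scores are
#' centered and eigenvalues non-increasing.
#'
#' @param tangent n x p matrix.
#' @return list with `scores` (n x r), `eigenvalues` (length r),
#'   `vectors` (p x r), `center`.
#' @export
shape_pca <- function(tangent) {
  tangent <- as.matrix(tangent)
  if (nrow(tangent) < 2) stop("need at least 2 specimens", call. = FALSE)
  pc <- stats::prcomp(tangent, center = TRUE, scale. = FALSE)
  r <- sum(pc$sdev^2 > max(pc$sdev^2) * 1e-12)
  list(scores = pc$x[, seq_len(r), drop = FALSE],
       eigenvalues = pc$sdev[seq_len(r)]^2,
       vectors = pc$rotation[, seq_len(r), drop = FALSE],
       center = pc$center)
}

#' Canonical variates analysis with PCA regularization
#'
#' Because landmark data have more variables than specimens, the tangent
#' data are first reduced by PCA to the smallest number of axes reaching
#' `retain_rule` of total variance (default 0.95), capped at n - g. The
#' canonical axes then solve the between-group / pooled within-group
#' eigenproblem on the reduced data; axes are scaled to unit pooled
#' within-group variance. `pct_differentiation` is each canonical
#' eigenvalue as a percentage of their sum.
#'
#' @inheritParams procrustes_anova
#' @param retain_rule fraction of variance the PCA reduction must reach.
#' @return object of class `cva_result`: `cv_scores` (n x n_axes),
#'   `pct_differentiation`, `eigenvalues`, `n_axes`, `group_means` (on the
#'   canonical axes), `labels`.
#' @export
cva <- function(tangent, labels, retain_rule = 0.95) {
  tangent <- as.matrix(tangent)
  labels <- droplevels(factor(labels))
  g <- nlevels(labels)
  if (g < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(labels) < 2))
    stop("each group needs at least 2 members", call. = FALSE)
  n <- nrow(tangent)
  pc <- shape_pca(tangent)
  cum <- cumsum(pc$eigenvalues) / sum(pc$eigenvalues)
  d <- min(which(cum >= retain_rule - 1e-12)[1], n - g, length(pc$eigenvalues))
  Z <- pc$scores[, seq_len(d), drop = FALSE]
  grand <- colMeans(Z)
  W <- matrix(0, d, d); B <- matrix(0, d, d)
  for (lv in levels(labels)) {
    Zg <- Z[labels == lv, , drop = FALSE]
    mg <- colMeans(Zg)
    W <- W + crossprod(sweep(Zg, 2, mg))
    B <- B + nrow(Zg) * tcrossprod(mg - grand)
  }
  W <- W / (n - g)
  ch <- tryCatch(chol(W), error = function(e)
    stop("singular within-group covariance after PCA reduction; ",
         "lower retain_rule", call. = FALSE))
  Li <- backsolve(ch, diag(d), transpose = TRUE)  # inv(t(chol)) = inv(L)
  Bs <- Li %*% B %*% t(Li)
  e <- eigen((Bs + t(Bs)) / 2, symmetric = TRUE)
  n_axes <- min(g - 1, d)
  vals <- pmax(e$values[seq_len(n_axes)], 0)
  A <- t(Li) %*% e$vectors[, seq_len(n_axes), drop = FALSE]
  # deterministic axis orientation: largest-magnitude loading positive
  for (j in seq_len(n_axes)) {
    i0 <- which.max(abs(A[, j]))
    if (A[i0, j] < 0) A[, j] <- -A[, j]
  }
  scores <- sweep(Z, 2, grand) %*% A
  colnames(scores) <- paste0("CV", seq_len(n_axes))
  gm <- do.call(rbind, lapply(levels(labels), function(lv)
    colMeans(scores[labels == lv, , drop = FALSE])))
  rownames(gm) <- levels(labels)
  structure(list(cv_scores = scores,
                 pct_differentiation = 100 * vals / sum(vals),
                 eigenvalues = vals, n_axes = n_axes, group_means = gm,
                 labels = labels),
            class = "cva_result")
}

#' @export
print.cva_result <- function(x, ...) {
  cat(sprintf("CVA: %d canonical axes; %% group differentiation: %s\n",
              x$n_axes,
              paste(sprintf("%.2f", x$pct_differentiation), collapse = ", ")))
  invisible(x)
}

#' Pairwise Procrustes distances between group mean shapes, with
#' permutation tests
#'
#' For each pair of groups the statistic is the full Procrustes distance
#' between the group mean shapes (group-mean tangent vectors mapped back to
#' configurations at the consensus); the p-value is the proportion of
#' within-pair label permutations with distance >= observed, with the
#' (b+1)/(m+1) correction. Pairs involving a single-specimen group get a
#' distance but a flagged (NA) p-value.
#'
#' @inheritParams procrustes_anova
#' @param consensus k x 3 consensus shape the tangent coordinates refer to.
#' @return object of class `pairwise_distance_table`: `distance` and
#'   `p_perm` (g x g symmetric matrices, zero/NA diagonal), `n_perm`,
#'   `seed`, `groups`.
#' @export
pairwise_shape_distances <- function(tangent, labels, consensus,
                                     n_perm = 10000, seed = 1) {
  tangent <- as.matrix(tangent)
  labels <- droplevels(factor(labels))
  g <- nlevels(labels)
  if (g < 2) stop("need at least 2 groups", call. = FALSE)
  lev <- levels(labels)
  dist_between <- function(Y, lab, l1, l2) {
    m1 <- colMeans(Y[lab == l1, , drop = FALSE])
    m2 <- colMeans(Y[lab == l2, , drop = FALSE])
    procrustes_distance(tangent_to_config(m1, consensus),
                        tangent_to_config(m2, consensus))
  }
  D <- matrix(0, g, g, dimnames = list(lev, lev))
  P <- matrix(NA_real_, g, g, dimnames = list(lev, lev))
  with_seed(seed, {
    for (i in seq_len(g - 1)) for (j in seq((i + 1), g)) {
      sel <- labels %in% lev[c(i, j)]
      Y <- tangent[sel, , drop = FALSE]
      lab <- droplevels(labels[sel])
      obs <- dist_between(Y, lab, lev[i], lev[j])
      D[i, j] <- D[j, i] <- obs
      n12 <- table(lab)[lev[c(i, j)]]
      if (all(n12 >= 2)) {
        null_d <- vapply(seq_len(n_perm), function(b)
          dist_between(Y, lab[sample.int(nrow(Y))], lev[i], lev[j]), 1.0)
        P[i, j] <- P[j, i] <- perm_pvalue(null_d, obs)
      }
    }
  })
  structure(list(distance = D, p_perm = P, n_perm = n_perm, seed = seed,
                 groups = lev),
            class = "pairwise_distance_table")
}

#' @export
print.pairwise_distance_table <- function(x, ...) {
  cat("Pairwise Procrustes distances (below diagonal) / permutation p (above):\n")
  M <- x$distance
  M[upper.tri(M)] <- x$p_perm[upper.tri(M)]
  print(round(M, 4))
  invisible(x)
}

#' Export a pairwise table in the distances-below / p-above layout
#'
#' @param x a `pairwise_distance_table`.
#' @param path CSV path.
#' @export
write_pairwise_csv <- function(x, path) {
  M <- x$distance
  M[upper.tri(M)] <- x$p_perm[upper.tri(M)]
  diag(M) <- NA
  utils::write.csv(data.frame(group = rownames(M), M, check.names = FALSE),
                   path, row.names = FALSE, na = "-")
  invisible(path)
}
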