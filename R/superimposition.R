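#' Centroid size of a configuration
#'
#' The square root of the summed squared distances of the landmarks to
#' their centroid — the standard geometric-morphometric size measure.
#'
#' @param coords k x 3 matrix (mm).
#' @return positive scalar (mm).
#' @export
centroid_size <- function(coords) {
  coords <- as_config_matrix(coords)
  if (nrow(coords) < 2) stop("need at least 2 landmarks", call. = FALSE)
  stopifnot_finite(coords, "configuration")
  cs <- sqrt(sum(sweep(coords, 2, colMeans(coords))^2))
  if (cs <= .Machine$double.eps^0.5)
    stop("degenerate configuration: all points coincident", call. = FALSE)
  cs
}

center_config <- function(x) sweep(x, 2, colMeans(x))

# optimal proper rotation R (det +1) minimizing ||a - b %*% R||_F for
# centered a, b; returns list(R, traced) where traced = sum of
# sign-corrected singular values of t(b) %*% a
kabsch <- function(a, b) {
  M <- crossprod(b, a)
  sv <- svd(M)
  s <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  list(R = R, traced = sum(sv$d * c(1, 1, s)))
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Finds the similarity transform (proper rotation, optional scale,
#' translation) minimizing the summed squared distances from the
#' transformed `b` to `a`. Reflections are never permitted.
#'
#' @param a,b k x 3 configurations with equal landmark counts, no missing
#'   points.
#' @param allow_scale fit a scale factor (default `TRUE`)?
#' @return list with `rotation` (3 x 3, det +1), `scale`, `translation`
#'   (so that `fitted = scale * b %*% rotation + translation`), `fitted`,
#'   and `residual` (root summed squared distance to `a`).
#' @export
procrustes_align <- function(a, b, allow_scale = TRUE) {
  a <- as_config_matrix(a); b <- as_config_matrix(b)
  if (nrow(a) != nrow(b)) stop("landmark counts differ", call. = FALSE)
  stopifnot_finite(a, "a"); stopifnot_finite(b, "b")
  ac <- center_config(a); bc <- center_config(b)
  if (qr(ac)$rank < 2 || qr(bc)$rank < 2)
    stop("degenerate (rank-deficient) configuration", call. = FALSE)
  kb <- kabsch(ac, bc)
  s <- if (allow_scale) kb$traced / sum(bc^2) else 1
  fitted_c <- s * bc %*% kb$R
  translation <- colMeans(a) - colMeans(s * b %*% kb$R)
  fitted <- sweep(s * b %*% kb$R, 2, translation, `+`)
  list(rotation = kb$R, scale = s, translation = translation,
       fitted = fitted, residual = sqrt(max(0, sum((ac - fitted_c)^2))))
}

# unit-centroid-size, centered version of a configuration (the "pre-shape")
preshape <- function(x) {
  xc <- center_config(as_config_matrix(x))
  xc / centroid_size(x)
}

#' Full Procrustes distance between two configurations
#'
#' Both configurations are centered and scaled to unit centroid size; the
#' full Procrustes distance sin(rho) is computed from the optimal proper
#' rotation (and scale) superimposing one on the other. Invariant to
#' translation, rotation and scaling of either argument; symmetric; zero
#' iff the shapes coincide.
#'
#' @param a,b k x 3 configurations.
#' @return scalar in [0, 1].
#' @export
procrustes_distance <- function(a, b) {
  pa <- preshape(a); pb <- preshape(b)
  cosr <- min(1, max(-1, kabsch(pa, pb)$traced))
  sqrt(max(0, 1 - cosr^2))
}

#' Generalized Procrustes superimposition
#'
#' Iterative superimposition removing translation, rotation and size: each
#' configuration is centered and scaled to unit centroid size, rotated to
#' the current consensus, and the consensus (mean shape, rescaled to unit
#' centroid size) is updated until it changes by less than `tol`
#' (root-summed-squared difference) or `max_iter` is reached. Original
#' centroid sizes (mm) are stored per specimen. Tangent-space coordinates
#' at the consensus are computed by [tangent_projection()].
#'
#' @param configs list of k x 3 matrices, or a k x 3 x n array, all
#'   complete, with equal landmark counts.
#' @param tol convergence tolerance on the consensus (default 1e-10).
#' @param max_iter iteration cap (default 100).
#' @return object of class `gpa_result`: `aligned` (k x 3 x n array, each
#'   at unit centroid size), `csize` (mm), `consensus` (k x 3, unit
#'   centroid size), `tangent` (n x 3k matrix), `iterations`, `converged`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100) {
  if (is.array(configs) && length(dim(configs)) == 3)
    configs <- lapply(seq_len(dim(configs)[3]), function(i) configs[, , i])
  n <- length(configs)
  if (n < 2) stop("need at least 2 configurations", call. = FALSE)
  k <- nrow(configs[[1]])
  if (any(vapply(configs, nrow, 1L) != k))
    stop("landmark counts differ across configurations", call. = FALSE)
  csize <- vapply(configs, centroid_size, 1.0)
  X <- array(NA_real_, c(k, 3, n))
  for (i in seq_len(n)) X[, , i] <- preshape(configs[[i]])
  consensus <- X[, , 1]
  iterations <- 0L
  converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    for (i in seq_len(n)) X[, , i] <- X[, , i] %*% kabsch(consensus, X[, , i])$R
    new_consensus <- apply(X, c(1, 2), mean)
    new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
    if (iterations >= max_iter) break
  }
  dimnames(X) <- list(rownames(configs[[1]]), c("x", "y", "z"), names(configs))
  res <- structure(list(aligned = X, csize = csize, consensus = consensus,
                        tangent = NULL, iterations = iterations,
                        converged = converged),
                   class = "gpa_result")
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations", call. = FALSE)
  res$tangent <- tangent_projection(res)
  res
}

#' @export
print.gpa_result <- function(x, ...) {
  cat(sprintf("GPA: %d specimens x %d landmarks; %d iterations (%s)\n",
              dim(x$aligned)[3], dim(x$aligned)[1], x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Tangent-space projection at the consensus
#'
#' Orthogonally projects the aligned unit-size configurations onto the
#' linear tangent space of shape space at the consensus: with x_i the
#' vectorised aligned shape and c the vectorised consensus (both unit
#' norm), the tangent coordinates are x_i - (x_i . c) c. The consensus
#' maps to the zero vector and the projection is idempotent.
#'
#' @param gpa_res a `gpa_result`.
#' @return n x 3k matrix of tangent coordinates.
#' @export
tangent_projection <- function(gpa_res) {
  stopifnot(inherits(gpa_res, "gpa_result"))
  n <- dim(gpa_res$aligned)[3]
  cvec <- as.vector(gpa_res$consensus)
  cvec <- cvec / sqrt(sum(cvec^2))
  Xm <- t(apply(gpa_res$aligned, 3, as.vector))
  dim(Xm) <- c(n, length(cvec))
  Xm - (Xm %*% cvec) %*% t(cvec)
}

# map tangent-space vectors back to k x 3 configurations at the consensus
tangent_to_config <- function(tvec, consensus) {
  cvec <- as.vector(consensus)
  matrix(cvec + as.vector(tvec), ncol = 3)
}
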