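#' Great-circle distance matrix between sites
#'
#' Haversine distances on a sphere of mean radius 6371.0088 km, from
#' decimal latitude/longitude.
#'
#' @param sites data frame with columns `site`, `latitude`, `longitude`.
#' @return symmetric km matrix with zero diagonal, dimnames = site names.
#' @export
site_distance_matrix <- function(sites) {
  sites <- as.data.frame(sites)
  if (any(!is.finite(sites$latitude)) || any(!is.finite(sites$longitude)) ||
      any(abs(sites$latitude) > 90) || any(abs(sites$longitude) > 180))
    stop("invalid decimal coordinates", call. = FALSE)
  p <- as.matrix(sites[, c("longitude", "latitude")])
  n <- nrow(p)
  m <- matrix(0, n, n, dimnames = list(sites$site, sites$site))
  for (i in seq_len(n)) {
    m[i, ] <- geosphere::distHaversine(p[i, ], p, r = 6371.0088)
  }
  diag(m) <- 0
  (m + t(m)) / 2
}

#' Equal-width geographic distance classes
#'
#' Bins every off-diagonal site pair into half-open classes [0, w),
#' [w, 2w), ... up to the class containing the maximum pairwise distance.
#' Empty classes are retained with zero pairs.
#'
#' @param distmat symmetric km matrix.
#' @param width_km class width (default 100 km).
#' @return data frame of class `distance_classes`: `class_id`, `lower_km`,
#'   `upper_km`, `n_pairs`, `mean_distance_km`; the pair membership is kept
#'   in `attr(, "pairs")` (list of 2-column index matrices).
#' @export
distance_classes <- function(distmat, width_km = 100) {
  if (width_km <= 0) stop("width must be positive", call. = FALSE)
  distmat <- as.matrix(distmat)
  n <- nrow(distmat)
  ut <- which(upper.tri(distmat), arr.ind = TRUE)
  dv <- distmat[upper.tri(distmat)]
  n_class <- max(1L, floor(max(dv) / width_km) + 1L)
  cls <- pmin(floor(dv / width_km) + 1L, n_class)
  pairs <- lapply(seq_len(n_class), function(ci)
    ut[cls == ci, , drop = FALSE])
  out <- data.frame(
    class_id = seq_len(n_class),
    lower_km = (seq_len(n_class) - 1) * width_km,
    upper_km = seq_len(n_class) * width_km,
    n_pairs = vapply(seq_len(n_class), function(ci) sum(cls == ci), 1L),
    mean_distance_km = vapply(seq_len(n_class), function(ci) {
      v <- dv[cls == ci]; if (length(v)) mean(v) else NA_real_
    }, 1.0))
  attr(out, "pairs") <- pairs
  attr(out, "sites") <- rownames(distmat)
  class(out) <- c("distance_classes", "data.frame")
  out
}

#' Moran's I spatial autocorrelation index
#'
#' I = (n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2, with W the sum of all weights. Deviations are from the plain
#' mean and the denominator is the maximum-likelihood variance estimate
#' (division by n). Weights here are binary class membership; they are not
#' row-standardized.
#'
#' @param values per-site numeric vector (no NAs).
#' @param weights symmetric, zero-diagonal weight matrix.
#' @return scalar I, or `NA` if the weight matrix has no nonzero entries.
#' @export
morans_i <- function(values, weights) {
  weights <- as.matrix(weights)
  n <- length(values)
  if (n < 2) stop("need at least 2 sites", call. = FALSE)
  if (nrow(weights) != n || ncol(weights) != n)
    stop("weight matrix dimension mismatch", call. = FALSE)
  if (any(abs(weights - t(weights)) > 1e-12) || any(diag(weights) != 0))
    stop("weights must be symmetric with zero diagonal", call. = FALSE)
  W <- sum(weights)
  if (W == 0) return(NA_real_)
  x <- values - mean(values)
  den <- sum(x^2)
  if (den == 0) stop("constant values: zero variance", call. = FALSE)
  (n / W) * as.numeric(t(x) %*% weights %*% x) / den
}

# Moran's I for many value vectors at once (columns of centered X)
morans_i_many <- function(Xc, weights) {
  W <- sum(weights)
  num <- colSums(Xc * (weights %*% Xc))
  den <- colSums(Xc^2)
  (nrow(Xc) / W) * num / den
}

#' Moran's I correlogram over geographic distance classes
#'
#' For each distance class, computes Moran's I over the sites that carry
#' data (sites with `NA` values are excluded pairwise) and a two-sided
#' permutation p-value around the null expectation -1/(n-1), shuffling
#' values across sites with the same permutations shared by all classes
#' within a replicate. Classes whose pairs all involve excluded sites are
#' flagged undefined (`NA`), matching the "-" convention of correlogram
#' tables for fragmentary samples.
#'
#' @param site_values named or distmat-ordered numeric vector (NA = site
#'   without data).
#' @param distmat symmetric km matrix (see [site_distance_matrix()] or the
#'   bundled [jomon_site_distances()]).
#' @param width_km class width in km (default 100).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param variable label stored with the result.
#' @return data frame of class `correlogram`: `class_id`,
#'   `mean_distance_km`, `n_pairs` (pairs among sites with data),
#'   `morans_i`, `p_perm`, `defined`.
#' @export
correlogram <- function(site_values, distmat, width_km = 100, n_perm = 999,
                        seed = 1, variable = "value") {
  distmat <- as.matrix(distmat)
  n_all <- nrow(distmat)
  if (length(site_values) != n_all)
    stop("site_values must align with distmat ordering", call. = FALSE)
  cl <- distance_classes(distmat, width_km)
  pairs <- attr(cl, "pairs")
  has_data <- which(!is.na(site_values))
  n <- length(has_data)
  if (n < 3) stop("need at least 3 sites with data", call. = FALSE)
  x <- site_values[has_data]
  if (stats::sd(x) == 0) stop("constant values: zero variance", call. = FALSE)
  expect_null <- -1 / (n - 1)
  perm_idx <- with_seed(seed, replicate(n_perm, sample.int(n)))
  Xp <- matrix(x[perm_idx], nrow = n)
  Xall <- cbind(x, Xp)
  Xall_c <- sweep(Xall, 2, colMeans(Xall))
  res <- lapply(seq_len(nrow(cl)), function(ci) {
    pm <- pairs[[ci]]
    keep <- pm[, 1] %in% has_data & pm[, 2] %in% has_data
    pm <- pm[keep, , drop = FALSE]
    if (nrow(pm) == 0)
      return(data.frame(class_id = ci, mean_distance_km = cl$mean_distance_km[ci],
                        n_pairs = 0L, morans_i = NA_real_, p_perm = NA_real_,
                        defined = FALSE))
    w <- matrix(0, n, n)
    i1 <- match(pm[, 1], has_data); i2 <- match(pm[, 2], has_data)
    w[cbind(i1, i2)] <- 1; w[cbind(i2, i1)] <- 1
    Iv <- morans_i_many(Xall_c, w)
    obs <- Iv[1]; null_i <- Iv[-1]
    p <- (sum(abs(null_i - expect_null) >= abs(obs - expect_null) - 1e-12) + 1) /
      (n_perm + 1)
    data.frame(class_id = ci, mean_distance_km = cl$mean_distance_km[ci],
               n_pairs = nrow(pm), morans_i = obs, p_perm = p, defined = TRUE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "variable") <- variable
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "n_sites") <- n
  class(out) <- c("correlogram", "data.frame")
  out
}

#' Per-site means of centroid size and PC scores
#'
#' Site-level summaries used by the spatial analyses: the arithmetic mean
#' of centroid size and of the first two PC scores over each site's
#' specimens.
#'
#' @param dataset the `annotated_dataset` whose specimens (in order) went
#'   into `gpa_res`.
#' @param gpa_res the corresponding [gpa()] result.
#' @return data frame: `site`, `n`, `csize`, `PC1`, `PC2` — one row per
#'   site of `dataset$sites`; sites with no specimens are excluded with a
#'   warning.
#' @export
site_summaries <- function(dataset, gpa_res) {
  if (length(dataset$specimens) != dim(gpa_res$aligned)[3])
    stop("dataset and GPA result differ in specimen count", call. = FALSE)
  pc <- shape_pca(gpa_res$tangent)
  sc <- pc$scores
  site <- vapply(dataset$specimens, `[[`, "", "site")
  all_sites <- dataset$sites$site
  empty <- setdiff(all_sites, unique(site))
  if (length(empty))
    warning("site(s) with no specimens excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
  keep <- intersect(all_sites, unique(site))
  out <- do.call(rbind, lapply(keep, function(s) {
    i <- which(site == s)
    data.frame(site = s, n = length(i), csize = mean(gpa_res$csize[i]),
               PC1 = mean(sc[i, 1]),
               PC2 = if (ncol(sc) >= 2) mean(sc[i, 2]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Bundled geographic distance matrix for the 16 Jomon sites (km)
#'
#' The published 16 x 16 between-site great-circle distance matrix for the
#' Jomon sites described by [jomon_sites()].
#'
#' @return symmetric 16 x 16 km matrix.
#' @export
jomon_site_distances <- function() {
  path <- system.file("extdata", "jomon_site_distances_km.csv",
                      package = "jomorph", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$site
  m
}

#' Bundled Jomon site table (synthetic coordinates)
#'
#' The 16 Jomon sites with their regional diet-group codes and per-site
#' sample sizes. The latitude/longitude columns are synthetic (plausible
#' arc positions along the Japanese Archipelago) because the source sites'
#' decimal coordinates are not published; use [jomon_site_distances()] for
#' the published between-site distances.
#'
#' @return data frame: `site`, `diet_group`, `n`, `latitude`, `longitude`.
#' @export
jomon_sites <- function() {
  path <- system.file("extdata", "jomon_sites_synthetic.csv",
                      package = "jomorph", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
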