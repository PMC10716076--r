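#' Simulation specification for synthetic skull-landmark data
#'
#' Defines the generative model used for testing the analysis pipeline:
#' each specimen's shape is the symmetric template pre-shape plus (i) a
#' per-diet-group tangent offset of stated norm, (ii) an allometric tangent
#' direction scaled by centred log size, (iii) a spatial cline along the
#' site arc, and isotropic Gaussian landmark noise in mm; the configuration
#' is then scaled to a log-normal centroid size, rigidly rotated and
#' translated, and landmarks are deleted missing-completely-at-random.
#'
#' The allometry magnitude is calibrated from `allometry_frac` so that,
#' with group effects and cline absent, the designed fraction of tangent
#' shape variance is attributable to size (using the small-noise relation
#' var_noise = (3k - 7) * (noise_sd / median size)^2 for the post-GPA
#' noise variance).
#'
#' @param sites data frame with `site`, `diet_group`, `n` (specimens per
#'   site), `latitude`, `longitude`; defaults to the bundled
#'   [jomon_sites()] table (16 sites, 5 diet groups, 85 specimens).
#' @param set_id landmark set to simulate (default `"neurocranial"`).
#' @param group_effect_norm tangent-space norm of each diet-group offset
#'   (default 0.03, of the order of observed between-group Procrustes
#'   distances).
#' @param allometry_frac designed fraction of shape variance explained by
#'   size (default 0.045).
#' @param size_meanlog,size_sdlog log-normal centroid-size distribution;
#'   `size_meanlog = NULL` centres sizes on the template's centroid size.
#' @param spatial_cline tangent-norm shape change per km along the site
#'   arc (default 0: no spatial structure).
#' @param noise_sd isotropic per-landmark-coordinate noise, mm (default 1).
#' @param missing_rate per-landmark MCAR deletion probability (default 0.05).
#' @param seed integer seed stored with the spec.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(sites = jomon_sites(),
                            set_id = "neurocranial",
                            group_effect_norm = 0.03,
                            allometry_frac = 0.045,
                            size_meanlog = NULL, size_sdlog = 0.05,
                            spatial_cline = 0,
                            noise_sd = 1, missing_rate = 0.05, seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate <= 1, noise_sd >= 0,
            allometry_frac >= 0, allometry_frac < 1)
  spec <- builtin_landmark_set(set_id)
  template <- make_template_skull(spec)
  if (is.null(size_meanlog)) size_meanlog <- log(centroid_size(template))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (!"n" %in% names(sites)) sites$n <- 5L
  structure(list(sites = sites, set_id = set_id, spec = spec,
                 template = template,
                 group_effect_norm = group_effect_norm,
                 allometry_frac = allometry_frac,
                 size_meanlog = size_meanlog, size_sdlog = size_sdlog,
                 spatial_cline = spatial_cline, noise_sd = noise_sd,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "simulation_spec")
}

# random proper rotation (QR of a Gaussian matrix, det forced to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# orthonormal basis of the non-shape subspace at pre-shape p0: scaling
# (p0 itself), the 3 translations, and the 3 infinitesimal rotations
nonshape_basis <- function(p0) {
  k <- nrow(p0)
  trans <- kronecker(diag(3), rep(1, k))
  gens <- list(rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0)),
               rbind(c(0, 0, -1), c(0, 0, 0), c(1, 0, 0)),
               rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0)))
  rots <- vapply(gens, function(G) as.vector(p0 %*% t(G)), numeric(3 * k))
  B <- cbind(as.vector(p0), trans, rots)
  qr.Q(qr(B))[, seq_len(qr(B)$rank), drop = FALSE]
}

# unit direction drawn uniformly within the shape-tangent subspace at p0
# (orthogonal to scaling, translation and rotation), so its full norm
# survives Procrustes superimposition
draw_tangent_direction <- function(p0vec, basis) {
  v <- stats::rnorm(length(p0vec))
  v <- v - basis %*% crossprod(basis, v)
  as.vector(v / sqrt(sum(v^2)))
}

#' Generate a synthetic annotated dataset with ground truth
#'
#' All draws come from one seeded generator in a fixed, documented order:
#' (1) one tangent direction per diet group, (2) the allometry direction,
#' (3) the cline direction, then (4) per specimen — size, landmark noise,
#' rotation, translation, missing mask — iterating sites in table order.
#' Identical specs (including seed) give byte-identical output.
#'
#' @param sim a [simulation_spec()].
#' @param seed overrides `sim$seed` when given.
#' @return list with `dataset` (an `annotated_dataset`) and `truth`
#'   (realized effect vectors, per-specimen true sizes and shapes, missing
#'   masks, per-site expected tangent means).
#' @export
generate_dataset <- function(sim, seed = sim$seed) {
  stopifnot(inherits(sim, "simulation_spec"))
  spec <- sim$spec
  k <- n_landmarks(spec)
  p0 <- preshape(sim$template)
  p0vec <- as.vector(p0)
  groups <- unique(sim$sites$diet_group)
  size_med <- exp(sim$size_meanlog)
  var_noise <- (3 * k - 7) * (sim$noise_sd / size_med)^2
  allo_mag <- if (sim$allometry_frac > 0 && sim$size_sdlog > 0)
    sqrt(sim$allometry_frac / (1 - sim$allometry_frac) * var_noise) /
      sim$size_sdlog else 0
  # site positions along the arc: great-circle distance from the first site
  arc_km <- as.numeric(geosphere::distHaversine(
    as.matrix(sim$sites[1, c("longitude", "latitude")]),
    as.matrix(sim$sites[, c("longitude", "latitude")]), r = 6371.0088))
  total_n <- sum(sim$sites$n)
  if (total_n * (1 - sim$missing_rate)^k < 2)
    warning("missing_rate so high that fewer than 2 complete specimens ",
            "are expected", call. = FALSE)
  basis <- nonshape_basis(p0)
  with_seed(seed, {
    geff <- lapply(groups, function(g)
      sim$group_effect_norm * draw_tangent_direction(p0vec, basis))
    names(geff) <- groups
    allo_dir <- draw_tangent_direction(p0vec, basis)
    cline_dir <- draw_tangent_direction(p0vec, basis)
    records <- list()
    truth_rows <- list()
    for (si in seq_len(nrow(sim$sites))) {
      site <- sim$sites$site[si]
      grp <- sim$sites$diet_group[si]
      for (ii in seq_len(sim$sites$n[si])) {
        s <- stats::rlnorm(1, sim$size_meanlog, sim$size_sdlog)
        tan_off <- geff[[grp]] +
          allo_mag * (log(s) - sim$size_meanlog) * allo_dir +
          sim$spatial_cline * arc_km[si] * cline_dir
        shape <- matrix(p0vec + tan_off, ncol = 3)
        config <- shape * s +
          matrix(stats::rnorm(3 * k, 0, sim$noise_sd), ncol = 3)
        R <- random_rotation()
        tr <- stats::runif(3, -100, 100)
        config <- sweep(config %*% R, 2, tr, `+`)
        miss <- stats::runif(k) < sim$missing_rate
        if (all(miss)) miss[1] <- FALSE
        id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", site), ii)
        sex <- sample(c("F", "M", "U"), 1, prob = c(0.4, 0.4, 0.2))
        config[miss, ] <- NA_real_
        rownames(config) <- spec$definitions$name
        records[[length(records) + 1L]] <-
          specimen_record(id, config, present = !miss, site = site, sex = sex)
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(specimen_id = id, site = site, diet_group = grp,
                     size = s, n_missing = sum(miss),
                     stringsAsFactors = FALSE)
      }
    }
    sites_tab <- sim$sites[, c("site", "diet_group", "latitude", "longitude")]
    dataset <- attach_metadata(records, sites_tab, spec)
    site_expect <- data.frame(
      site = sim$sites$site, arc_km = arc_km,
      cline_component = sim$spatial_cline * arc_km,
      stringsAsFactors = FALSE)
    list(dataset = dataset,
         truth = list(group_effects = geff,
                      allometry_direction = allo_dir,
                      allometry_magnitude = allo_mag,
                      cline_direction = cline_dir,
                      spatial_cline = sim$spatial_cline,
                      specimens = do.call(rbind, truth_rows),
                      site_expect = site_expect,
                      template = sim$template, seed = seed))
  })
}

#' Convenience: the bundled 16-site simulation
#'
#' A [simulation_spec()] on the bundled Jomon site structure (16 sites,
#' five diet groups, per-site sample sizes 1-20, 85 specimens in total).
#'
#' @inheritParams simulation_spec
#' @param ... passed to [simulation_spec()].
#' @export
jomon_simulation <- function(set_id = "neurocranial", ...) {
  simulation_spec(sites = jomon_sites(), set_id = set_id, ...)
}

#' A linear transect site layout for spatial simulations
#'
#' Evenly spaced sites along a south-north transect, used to exercise
#' isolation-by-distance patterns.
#'
#' @param n_sites number of sites (default 8).
#' @param length_km transect length (default 700).
#' @param diet_group diet code assigned to all sites.
#' @param n_per_site specimens per site.
#' @return site data frame usable in [simulation_spec()].
#' @export
transect_sites <- function(n_sites = 8, length_km = 700, diet_group = "CCH",
                           n_per_site = 5) {
  lat0 <- 34
  dlat <- (length_km / 6371.0088) * (180 / pi)
  data.frame(site = sprintf("T%02d", seq_len(n_sites)),
             diet_group = diet_group,
             n = n_per_site,
             latitude = lat0 + seq(0, dlat, length.out = n_sites),
             longitude = 138, stringsAsFactors = FALSE)
}
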