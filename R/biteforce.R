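#' Landmark roles for bite-force estimation
#'
#' Index sets mapping the bite-force landmark set onto the biomechanical
#' model: temporalis muscle points (landmarks 2-4 and 9-12 plus
#' semilandmarks 16-26), masseter muscle points (landmark 1 and 5-8 plus
#' semilandmarks 13-15), the temporomandibular joint (TMJ, the fulcrum),
#' and the M2 bite point. Muscle sets must be disjoint from the TMJ and
#' bite-point indices.
#'
#' @param temporalis,masseter integer index vectors.
#' @param tmj,bitepoint scalar indices.
#' @return list of class `biteforce_roles`.
#' @export
biteforce_roles <- function(temporalis = c(2:4, 9:12, 16:26),
                            masseter = c(1, 5:8, 13:15),
                            tmj = 27, bitepoint = 28) {
  temporalis <- as.integer(temporalis); masseter <- as.integer(masseter)
  tmj <- as.integer(tmj); bitepoint <- as.integer(bitepoint)
  if (length(intersect(c(temporalis, masseter), c(tmj, bitepoint))))
    stop("muscle index sets must be disjoint from TMJ and bite point",
         call. = FALSE)
  if (tmj == bitepoint) stop("TMJ and bite point must differ", call. = FALSE)
  structure(list(temporalis = temporalis, masseter = masseter, tmj = tmj,
                 bitepoint = bitepoint), class = "biteforce_roles")
}

#' Estimate relative bite force from cranial landmarks
#'
#' Computes BF = (TCS * t + MCS * m) / Mo, where TCS and MCS are the
#' centroid sizes (mm) of the temporalis and masseter landmark+semilandmark
#' subsets, t and m are the lever arms from each muscle subset's centroid
#' to the TMJ (mm), and Mo is the moment arm from the TMJ to the M2 bite
#' point (mm). All arms are 3D Euclidean distances between landmark-derived
#' points; raw millimetre coordinates are used so BF carries size
#' information. BF is a dimensionless relative score (mm^2 scale) for
#' comparative use, not an absolute force.
#'
#' @param record a complete [specimen_record()] on the bite-force set (or a
#'   k x 3 matrix).
#' @param roles a [biteforce_roles()] map.
#' @return one-row data frame of class `biteforce_result`: `specimen_id`,
#'   `TCS`, `MCS`, `t`, `m`, `Mo`, `BF`.
#' @export
estimate_bite_force <- function(record, roles = biteforce_roles()) {
  if (inherits(record, "specimen_record")) {
    co <- record$coords
    need <- c(roles$temporalis, roles$masseter, roles$tmj, roles$bitepoint)
    if (!all(record$present[need]))
      stop("missing role landmarks at indices: ",
           paste(need[!record$present[need]], collapse = ", "), call. = FALSE)
    id <- record$specimen_id
  } else {
    co <- as_config_matrix(record)
    id <- NA_character_
  }
  tcs <- centroid_size(co[roles$temporalis, , drop = FALSE])
  mcs <- centroid_size(co[roles$masseter, , drop = FALSE])
  tmj <- co[roles$tmj, ]
  bite <- co[roles$bitepoint, ]
  tc <- colMeans(co[roles$temporalis, , drop = FALSE])
  mc <- colMeans(co[roles$masseter, , drop = FALSE])
  t_arm <- sqrt(sum((tc - tmj)^2))
  m_arm <- sqrt(sum((mc - tmj)^2))
  mo <- sqrt(sum((tmj - bite)^2))
  if (mo <= 0) stop("degenerate moment arm (TMJ coincides with bite point)",
                    call. = FALSE)
  structure(data.frame(specimen_id = id, TCS = tcs, MCS = mcs, t = t_arm,
                       m = m_arm, Mo = mo,
                       BF = (tcs * t_arm + mcs * m_arm) / mo,
                       stringsAsFactors = FALSE),
            class = c("biteforce_result", "data.frame"))
}

#' Bite-force table for a dataset
#'
#' @param dataset an `annotated_dataset` on the bite-force landmark set,
#'   already subset to complete specimens.
#' @param roles a [biteforce_roles()] map.
#' @return data frame with specimen metadata and BF components.
#' @export
biteforce_table <- function(dataset, roles = biteforce_roles()) {
  rows <- lapply(dataset$specimens, function(r) {
    out <- estimate_bite_force(r, roles)
    out$site <- r$site
    out$sex <- r$sex
    out
  })
  out <- do.call(rbind, rows)
  out$diet_group <- dataset$sites$diet_group[match(out$site, dataset$sites$site)]
  out[, c("specimen_id", "site", "diet_group", "sex", "TCS", "MCS", "t", "m",
          "Mo", "BF")]
}

#' Univariate group comparison with assumption checks
#'
#' The comparison pipeline used for bite force: (i) groups with fewer than
#' 2 members are dropped and recorded; (ii) Shapiro-Wilk normality per
#' group (needs n >= 3; smaller groups reported as NA); (iii)
#' Brown-Forsythe Levene test (median-centered); (iv) Welch's F (with
#' Welch-Satterthwaite df) if Levene p < 0.05, classical one-way F
#' otherwise; (v) Tukey HSD post-hoc over all retained pairs. The report is
#' fully deterministic given the data.
#'
#' @param values numeric vector.
#' @param labels group factor.
#' @param alpha significance level for the Levene branch rule (default 0.05).
#' @return list of class `group_comparison`: `method` ("welch" or
#'   "classical"), `F`, `df`, `p`, `levene`, `shapiro` (per-group data
#'   frame), `tukey` (pairwise data frame), `dropped_groups`, `n_by_group`.
#' @export
compare_groups_univariate <- function(values, labels, alpha = 0.05) {
  labels <- factor(labels)
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- droplevels(labels[ok])
  sizes <- table(labels)
  dropped <- names(sizes)[sizes < 2]
  keep <- !(labels %in% dropped)
  values <- values[keep]
  labels <- droplevels(labels[keep])
  if (nlevels(labels) < 2)
    stop("fewer than 2 groups with >= 2 members", call. = FALSE)
  shapiro <- do.call(rbind, lapply(levels(labels), function(lv) {
    v <- values[labels == lv]
    if (length(v) >= 3 && stats::sd(v) > 0) {
      sw <- stats::shapiro.test(v)
      data.frame(group = lv, n = length(v), W = unname(sw$statistic),
                 p = sw$p.value)
    } else data.frame(group = lv, n = length(v), W = NA_real_, p = NA_real_)
  }))
  lev <- car::leveneTest(values ~ labels, center = stats::median)
  lev_p <- lev[["Pr(>F)"]][1]
  use_welch <- is.finite(lev_p) && lev_p < alpha
  ow <- stats::oneway.test(values ~ labels, var.equal = !use_welch)
  tk <- stats::TukeyHSD(stats::aov(values ~ labels))$labels
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  structure(list(method = if (use_welch) "welch" else "classical",
                 F = unname(ow$statistic),
                 df = unname(ow$parameter),
                 p = ow$p.value,
                 levene = list(F = lev[["F value"]][1], p = lev_p),
                 shapiro = shapiro, tukey = tukey,
                 dropped_groups = dropped,
                 n_by_group = table(labels)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s one-way test: F = %.4f (df %s), p = %.4g; Levene p = %.4g\n",
              if (x$method == "welch") "Welch" else "Classical",
              x$F, paste(signif(x$df, 4), collapse = ", "), x$p, x$levene$p))
  if (length(x$dropped_groups))
    cat("dropped (n < 2):", paste(x$dropped_groups, collapse = ", "), "\n")
  invisible(x)
}
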