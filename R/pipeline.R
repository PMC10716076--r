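#' Pipeline configuration
#'
#' Bundles the choices driving [run_pipeline()]: which landmark sets to
#' analyse, which analysis stages to run, permutation counts and the
#' global seed (mandatory, since every stage past input parsing is
#' stochastic). Per-stage seeds are derived by hashing the stage name into
#' the global seed, so disabling one stage never perturbs another's
#' randomness. A configuration can also be read from a YAML file with the
#' same field names.
#'
#' @param sets landmark sets to analyse.
#' @param analyses stages to run, among `"preliminary"`, `"diet"`,
#'   `"spatial"`.
#' @param n_perm permutations for all permutation tests.
#' @param seed global integer seed.
#' @param width_km distance-class width for correlograms.
#' @param max_missing imputation threshold (see
#'   [impute_missing_bilateral()]).
#' @param out_dir optional directory: when set, all report tables are
#'   written there as full-precision CSV.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sets = c("craniofacial", "facial", "neurocranial",
                                     "temporalis", "biteforce"),
                            analyses = c("preliminary", "diet", "spatial"),
                            n_perm = 999, seed = 1, width_km = 100,
                            max_missing = 3, out_dir = NULL) {
  sets <- match.arg(sets, several.ok = TRUE)
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(list(sets = sets, analyses = analyses, n_perm = n_perm,
                 seed = as.integer(seed), width_km = width_km,
                 max_missing = max_missing, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any of the [pipeline_config()] fields.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y),
                                       names(formals(pipeline_config)))])
}

#' Simulate a full multi-set study
#'
#' Generates one synthetic dataset per requested landmark set on a shared
#' site structure (the facial set is carved out of the craniofacial
#' dataset downstream, so it shares specimens, as it does anatomically).
#'
#' @param sets landmark sets to simulate (facial is derived, not simulated).
#' @param seed global seed; per-set seeds are derived from it.
#' @param sites site table (default [jomon_sites()]).
#' @param ... passed to [simulation_spec()].
#' @return named list of `annotated_dataset`s.
#' @export
simulate_study <- function(sets = c("craniofacial", "neurocranial",
                                    "temporalis", "biteforce"),
                           seed = 1, sites = jomon_sites(), ...) {
  sets <- setdiff(sets, "facial")
  out <- lapply(sets, function(sid) {
    sim <- simulation_spec(sites = sites, set_id = sid, ...)
    generate_dataset(sim, seed = derive_seed(seed, paste0("simulate_", sid)))$dataset
  })
  names(out) <- sets
  out
}

pipeline_log <- function(report, msg) {
  report$log <- c(report$log, msg)
  report
}

# diet labels with small groups dropped for tests requiring >= min_n per group
drop_small_groups <- function(labels, min_n = 2) {
  labels <- factor(labels)
  sizes <- table(labels)
  keep <- labels %in% names(sizes)[sizes >= min_n]
  list(keep = keep, labels = droplevels(labels[keep]),
       dropped = names(sizes)[sizes < min_n])
}

#' Run the full analysis pipeline
#'
#' Orchestrates the study sequence on annotated landmark datasets:
#' mirror imputation and completeness reporting, per-set subsetting to
#' complete specimens, generalized Procrustes superimposition, preliminary
#' analyses (shape-on-size regression, sex Procrustes ANOVA, bite-force
#' sex comparison), diet analyses (permutation MANOVA, CVA, pairwise
#' Procrustes-distance tests, bite-force diet comparison), and spatial
#' analyses (site summaries and Moran's I correlograms for centroid size
#' and PC1/PC2). Every exclusion decision is logged in `report$log`.
#'
#' @param datasets named list of raw `annotated_dataset`s keyed by set id
#'   (as from [simulate_study()]); a `"facial"` entry is derived from
#'   `"craniofacial"` when requested but absent.
#' @param config a [pipeline_config()].
#' @return list of class `run_report` with per-stage results and
#'   provenance; rerunning an identical config on identical data yields
#'   identical tables.
#' @export
run_pipeline <- function(datasets, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(log = character(), config = config,
                 provenance = list(seed = config$seed, n_perm = config$n_perm,
                                   package_version =
                                     as.character(utils::packageVersion("jomorph"))))
  # ---- impute + subset -------------------------------------------------
  completeness <- list()
  complete <- list()
  gpas <- list()
  for (sid in config$sets) {
    src <- if (sid %in% names(datasets)) datasets[[sid]]
           else if (sid == "facial" && "craniofacial" %in% names(datasets))
             datasets[["craniofacial"]]
           else stop("no dataset for landmark set '", sid, "'", call. = FALSE)
    imp <- impute_dataset(src, max_missing = config$max_missing)
    target <- builtin_landmark_set(sid)
    ds <- subset_complete(imp$dataset, target)
    completeness[[sid]] <- imp$report
    complete[[sid]] <- ds
    excluded <- setdiff(vapply(src$specimens, `[[`, "", "specimen_id"),
                        vapply(ds$specimens, `[[`, "", "specimen_id"))
    report <- pipeline_log(report, sprintf(
      "%s: %d/%d specimens complete after imputation%s", sid,
      length(ds$specimens), length(src$specimens),
      if (length(excluded)) paste0("; excluded: ",
                                   paste(excluded, collapse = ", ")) else ""))
    if (sid != "biteforce" && length(ds$specimens) >= 2)
      gpas[[sid]] <- gpa(dataset_array(ds))
  }
  report$completeness <- completeness
  shape_sets <- setdiff(intersect(config$sets, names(gpas)), "biteforce")
  bf_tab <- NULL
  if ("biteforce" %in% config$sets && length(complete$biteforce$specimens) >= 2)
    bf_tab <- biteforce_table(complete$biteforce)
  report$biteforce <- bf_tab
  # ---- preliminary -----------------------------------------------------
  if ("preliminary" %in% config$analyses) {
    prelim <- list()
    for (sid in shape_sets) {
      g <- gpas[[sid]]
      sd_ <- derive_seed(config$seed, paste0("preliminary_", sid))
      reg <- shape_size_regression(g$tangent, log(g$csize),
                                   n_perm = config$n_perm, seed = sd_)
      sex <- vapply(complete[[sid]]$specimens, `[[`, "", "sex")
      dg <- drop_small_groups(sex)
      sex_test <- NULL
      if (nlevels(dg$labels) >= 2) {
        sex_test <- procrustes_anova(g$tangent[dg$keep, , drop = FALSE],
                                     dg$labels, n_perm = config$n_perm,
                                     seed = derive_seed(config$seed,
                                                        paste0("sex_", sid)))
        if (length(dg$dropped))
          report <- pipeline_log(report, sprintf(
            "%s sex ANOVA: dropped sex group(s) with n < 2: %s", sid,
            paste(dg$dropped, collapse = ", ")))
      }
      prelim[[sid]] <- list(size_regression = reg, sex_anova = sex_test)
    }
    if (!is.null(bf_tab)) {
      prelim$biteforce_sex <- tryCatch(
        compare_groups_univariate(bf_tab$BF, bf_tab$sex),
        error = function(e) NULL)
    }
    sex_ps <- unlist(lapply(prelim[shape_sets], function(x)
      if (!is.null(x$sex_anova)) x$sex_anova$p_perm else NULL))
    if (length(sex_ps) && all(sex_ps >= 0.05))
      report <- pipeline_log(report,
        "no significant sexual dimorphism in any shape set; sexes pooled for subsequent analyses")
    report$preliminary <- prelim
  }
  # ---- diet ------------------------------------------------------------
  if ("diet" %in% config$analyses) {
    diet <- list()
    for (sid in shape_sets) {
      g <- gpas[[sid]]
      grp <- specimen_diet(complete[[sid]])
      dg <- drop_small_groups(grp)
      if (length(dg$dropped))
        report <- pipeline_log(report, sprintf(
          "%s diet tests: group(s) with n < 2 dropped from MANOVA/CVA: %s",
          sid, paste(dg$dropped, collapse = ", ")))
      res <- list()
      if (nlevels(dg$labels) >= 2) {
        tan2 <- g$tangent[dg$keep, , drop = FALSE]
        res$manova <- procrustes_anova(tan2, dg$labels,
                                       n_perm = config$n_perm,
                                       seed = derive_seed(config$seed,
                                                          paste0("diet_manova_", sid)))
        res$cva <- tryCatch(cva(tan2, dg$labels), error = function(e) {
          report <<- pipeline_log(report, sprintf("%s CVA failed: %s", sid,
                                                  conditionMessage(e)))
          NULL
        })
      }
      res$pairwise <- pairwise_shape_distances(
        g$tangent, grp, g$consensus, n_perm = config$n_perm,
        seed = derive_seed(config$seed, paste0("diet_pairwise_", sid)))
      diet[[sid]] <- res
    }
    if (!is.null(bf_tab)) {
      diet$biteforce <- tryCatch(
        compare_groups_univariate(bf_tab$BF, bf_tab$diet_group),
        error = function(e) NULL)
      if (!is.null(diet$biteforce) && length(diet$biteforce$dropped_groups))
        report <- pipeline_log(report, sprintf(
          "bite-force ANOVA: group(s) not included as > 1 individual is required: %s",
          paste(diet$biteforce$dropped_groups, collapse = ", ")))
    }
    report$diet <- diet
  }
  # ---- spatial ---------------------------------------------------------
  if ("spatial" %in% config$analyses) {
    spatial <- list()
    for (sid in shape_sets) {
      ds <- complete[[sid]]
      summ <- withCallingHandlers(
        site_summaries(ds, gpas[[sid]]),
        warning = function(w) {
          report <<- pipeline_log(report, sprintf("%s spatial: %s", sid,
                                                  conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      distmat <- site_distance_matrix(ds$sites)
      vals <- function(col) {
        v <- summ[[col]][match(rownames(distmat), summ$site)]
        v
      }
      sd_ <- derive_seed(config$seed, paste0("spatial_", sid))
      spatial[[sid]] <- list(
        site_summaries = summ,
        csize = correlogram(vals("csize"), distmat, config$width_km,
                            config$n_perm, sd_, variable = "csize"),
        PC1 = correlogram(vals("PC1"), distmat, config$width_km,
                          config$n_perm, sd_, variable = "PC1"),
        PC2 = correlogram(vals("PC2"), distmat, config$width_km,
                          config$n_perm, sd_, variable = "PC2"))
    }
    report$spatial <- spatial
  }
  report$gpa <- gpas
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$provenance$seed, ")\n")
  for (m in x$log) cat(" -", m, "\n")
  invisible(x)
}

#' Write all report tables as CSV
#'
#' Tables are written full-precision; file names are keyed by stage and
#' landmark set. Rerunning an identical configuration reproduces the files
#' byte-for-byte.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE, na = "-")
  write_completeness_csv(report$completeness,
                         file.path(dir, "completeness.csv"))
  if (!is.null(report$biteforce)) w(report$biteforce, "biteforce")
  if (!is.null(report$preliminary)) {
    rows <- list()
    for (sid in names(report$preliminary)) {
      p <- report$preliminary[[sid]]
      if (!is.list(p) || is.null(p$size_regression)) next
      reg <- p$size_regression
      rows[[sid]] <- data.frame(
        set = sid, F = reg$F, r2 = reg$r2, pct_explained = reg$pct_explained,
        p_perm = reg$p_perm,
        sex_F = if (!is.null(p$sex_anova)) p$sex_anova$F else NA,
        sex_p = if (!is.null(p$sex_anova)) p$sex_anova$p_perm else NA)
    }
    w(do.call(rbind, rows), "preliminary")
  }
  if (!is.null(report$diet)) {
    for (sid in setdiff(names(report$diet), "biteforce")) {
      d <- report$diet[[sid]]
      if (!is.null(d$pairwise))
        write_pairwise_csv(d$pairwise, file.path(dir,
                                                 paste0("pairwise_", sid, ".csv")))
      if (!is.null(d$cva)) {
        ids <- rownames(d$cva$cv_scores)
        if (is.null(ids)) ids <- seq_len(nrow(d$cva$cv_scores))
        w(data.frame(specimen = ids, d$cva$cv_scores,
                     group = d$cva$labels), paste0("cva_scores_", sid))
      }
    }
  }
  if (!is.null(report$spatial)) {
    for (sid in names(report$spatial)) {
      s <- report$spatial[[sid]]
      w(s$site_summaries, paste0("site_summaries_", sid))
      corr <- rbind(cbind(variable = "csize", as.data.frame(s$csize)),
                    cbind(variable = "PC1", as.data.frame(s$PC1)),
                    cbind(variable = "PC2", as.data.frame(s$PC2)))
      w(corr, paste0("correlogram_", sid))
    }
  }
  invisible(dir)
}
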