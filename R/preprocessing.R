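#' Estimate a specimen's midline (sagittal) plane
#'
#' Fits the least-squares symmetry plane from the specimen's own landmarks:
#' present midline landmarks should lie on the plane, and each complete
#' bilateral pair should be mirror-symmetric about it (pair midpoint on the
#' plane, pair difference vector parallel to the normal). The objective is
#' solved in closed form by an eigen-decomposition: writing C for the
#' scatter of on-plane points (midline landmarks and pair midpoints about
#' their mean) and D for the sum of outer products of pair difference
#' vectors, the optimal unit normal is the eigenvector of C - D with the
#' smallest eigenvalue. The sign of the normal is fixed so that its first
#' component of magnitude > 1e-9 is positive.
#'
#' @param record a [specimen_record()].
#' @param spec the record's [landmark_set()].
#' @return list with `point` (3-vector on the plane) and `normal`
#'   (unit 3-vector), class `midline_plane`.
#' @export
estimate_midline <- function(record, spec) {
  d <- spec$definitions
  pres <- record$present
  mid_idx <- which(d$laterality == "midline" & pres)
  pair_rows <- which(!is.na(d$partner) & d$index < d$partner)
  pair_rows <- pair_rows[pres[pair_rows] & pres[d$partner[pair_rows]]]
  Qm <- record$coords[mid_idx, , drop = FALSE]
  if (length(pair_rows)) {
    A <- record$coords[pair_rows, , drop = FALSE]
    B <- record$coords[d$partner[pair_rows], , drop = FALSE]
    mids <- (A + B) / 2
    diffs <- A - B
  } else {
    mids <- matrix(0, 0, 3); diffs <- matrix(0, 0, 3)
  }
  Q <- rbind(Qm, mids)
  if (nrow(Q) == 0)
    stop("no symmetry information: no midline landmarks or complete pairs",
         call. = FALSE)
  qbar <- colMeans(Q)
  Qc <- sweep(Q, 2, qbar)
  C <- crossprod(Qc)
  D <- if (nrow(diffs)) crossprod(diffs) else matrix(0, 3, 3)
  if (nrow(diffs) == 0) {
    # midline landmarks only: need >= 3 non-collinear points for a unique plane
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (nrow(Q) < 3 || ev[2] <= 1e-10 * max(ev[1], 1))
      stop("insufficient symmetry information: midline landmarks are ",
           "fewer than 3 or collinear", call. = FALSE)
  }
  e <- eigen(C - D, symmetric = TRUE)
  normal <- e$vectors[, 3]
  j <- which(abs(normal) > 1e-9)[1]
  if (normal[j] < 0) normal <- -normal
  structure(list(point = qbar, normal = normal / sqrt(sum(normal^2))),
            class = "midline_plane")
}

reflect_points <- function(x, plane) {
  n <- plane$normal
  x - 2 * ((sweep(x, 2, plane$point) %*% n) %*% t(n))
}

#' Reflect a specimen through a plane, preserving anatomical sides
#'
#' Mirrors every landmark through `plane`, then swaps the rows of each
#' bilateral pair so that left/right labels keep their anatomical meaning.
#' Centroid size is preserved (reflection is an isometry).
#'
#' @inheritParams estimate_midline
#' @param plane a `midline_plane` (from [estimate_midline()]) or a list with
#'   `point` and `normal`.
#' @return the reflected [specimen_record()].
#' @export
reflect_configuration <- function(record, spec, plane) {
  nn <- sqrt(sum(plane$normal^2))
  if (nn == 0) stop("plane normal must be nonzero", call. = FALSE)
  plane$normal <- plane$normal / nn
  co <- record$coords
  pres <- record$present
  co[pres, ] <- reflect_points(co[pres, , drop = FALSE], plane)
  d <- spec$definitions
  swap <- seq_len(nrow(d))
  has_p <- !is.na(d$partner)
  swap[has_p] <- d$partner[has_p]
  record$coords <- co[swap, , drop = FALSE]
  record$present <- pres[swap]
  record$imputed <- record$imputed[swap]
  rownames(record$coords) <- d$name
  record
}

#' Impute missing bilateral landmarks by midline mirroring
#'
#' Each missing landmark whose bilateral partner is present is replaced by
#' the partner's reflection through the specimen's estimated midline plane
#' and flagged imputed. Specimens missing more than `max_missing` landmarks
#' (default 3, i.e. imputation only where fewer than four are missing) are
#' returned unchanged and flagged excluded. Missing midline landmarks,
#' unpaired lateral landmarks, and pairs missing on both sides are never
#' imputed; such cases are reported, not raised.
#'
#' @inheritParams estimate_midline
#' @param max_missing maximum number of missing landmarks for which
#'   imputation is attempted.
#' @return list with `record` (possibly updated) and `report` (one-row data
#'   frame: `specimen_id`, `n_missing_before`, `n_imputed`,
#'   `n_missing_after`, `excluded`, `complete`).
#' @export
impute_missing_bilateral <- function(record, spec, max_missing = 3) {
  nb <- n_missing(record)
  d <- spec$definitions
  rep_row <- function(rec, n_imp, excl) {
    data.frame(specimen_id = rec$specimen_id, n_missing_before = nb,
               n_imputed = n_imp, n_missing_after = n_missing(rec),
               excluded = excl, complete = all(rec$present),
               stringsAsFactors = FALSE)
  }
  if (nb == 0 || nb > max_missing)
    return(list(record = record,
                report = rep_row(record, 0L, nb > max_missing)))
  imputable <- which(!record$present & !is.na(d$partner) &
                       record$present[ifelse(is.na(d$partner), 1L, d$partner)])
  if (length(imputable) == 0)
    return(list(record = record, report = rep_row(record, 0L, FALSE)))
  plane <- tryCatch(estimate_midline(record, spec), error = function(e) NULL)
  if (is.null(plane))
    return(list(record = record, report = rep_row(record, 0L, FALSE)))
  for (i in imputable) {
    src <- record$coords[d$partner[i], , drop = FALSE]
    record$coords[i, ] <- reflect_points(src, plane)
    record$present[i] <- TRUE
    record$imputed[i] <- TRUE
  }
  list(record = record, report = rep_row(record, length(imputable), FALSE))
}

#' Impute an entire dataset
#'
#' Applies [impute_missing_bilateral()] to each specimen and collects the
#' per-specimen completeness report.
#'
#' @param dataset an `annotated_dataset`.
#' @inheritParams impute_missing_bilateral
#' @return list with `dataset` (records updated) and `report` (data frame).
#' @export
impute_dataset <- function(dataset, max_missing = 3) {
  out <- lapply(dataset$specimens, impute_missing_bilateral,
                spec = dataset$spec, max_missing = max_missing)
  dataset$specimens <- lapply(out, `[[`, "record")
  list(dataset = dataset, report = do.call(rbind, lapply(out, `[[`, "report")))
}

#' Subset a dataset to specimens complete for a target landmark set
#'
#' Landmarks are matched by name between the dataset's set and
#' `target_spec` (e.g. the facial set names a subset of the craniofacial
#' set). Only specimens with all target landmarks present (post-imputation)
#' are retained, with coordinates reordered to follow `target_spec`.
#'
#' @param dataset an `annotated_dataset`.
#' @param target_spec a [landmark_set()] whose landmark names all occur in
#'   the dataset's set.
#' @return an `annotated_dataset` on `target_spec`.
#' @export
subset_complete <- function(dataset, target_spec = dataset$spec) {
  idx <- match(target_spec$definitions$name, dataset$spec$definitions$name)
  if (any(is.na(idx)))
    stop("target landmarks not in dataset set: ",
         paste(target_spec$definitions$name[is.na(idx)], collapse = ", "),
         call. = FALSE)
  keep <- vapply(dataset$specimens, function(r) all(r$present[idx]), TRUE)
  recs <- lapply(dataset$specimens[keep], function(r) {
    r$coords <- r$coords[idx, , drop = FALSE]
    rownames(r$coords) <- target_spec$definitions$name
    r$present <- r$present[idx]
    r$imputed <- r$imputed[idx]
    r
  })
  if (length(recs) == 0)
    warning("no specimens complete for landmark set '", target_spec$set_id,
            "'", call. = FALSE)
  structure(list(spec = target_spec, specimens = recs, sites = dataset$sites),
            class = "annotated_dataset")
}

#' Write a completeness report CSV
#'
#' One row per specimen with missing/imputed counts and an inclusion flag
#' per analysed landmark set, mirroring the usual supplementary
#' preservation table of fragmentary cranial samples.
#'
#' @param reports named list of per-set report data frames (as returned by
#'   [impute_dataset()]), names used as column suffixes.
#' @param path output CSV path.
#' @export
write_completeness_csv <- function(reports, path) {
  ids <- sort(unique(unlist(lapply(reports, `[[`, "specimen_id"))))
  out <- data.frame(specimen_id = ids, stringsAsFactors = FALSE)
  for (nm in names(reports)) {
    r <- reports[[nm]]
    i <- match(ids, r$specimen_id)
    out[[paste0("n_missing_before_", nm)]] <- r$n_missing_before[i]
    out[[paste0("n_imputed_", nm)]] <- r$n_imputed[i]
    out[[paste0("included_", nm)]] <- r$complete[i]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
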