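#' Specimen records and annotated datasets
#'
#' A `specimen_record` holds one specimen's 3D landmark coordinates (mm) with
#' a per-landmark presence mask; an `annotated_dataset` bundles records with
#' a landmark-set specification and per-site metadata (diet group, decimal
#' coordinates).
#'
#' @param specimen_id character scalar.
#' @param coords k x 3 numeric matrix; rows of missing landmarks may be `NA`.
#' @param present logical length-k mask; defaults to rows with all-finite
#'   coordinates.
#' @param site,sex optional metadata (`sex` one of `"F"`, `"M"`, `"U"`).
#' @param imputed logical mask flagging mirror-imputed landmarks.
#' @return an object of class `specimen_record`.
#' @export
specimen_record <- function(specimen_id, coords, present = NULL,
                            site = NA_character_, sex = "U", imputed = NULL) {
  coords <- as_config_matrix(coords)
  k <- nrow(coords)
  if (is.null(present)) present <- apply(is.finite(coords), 1, all)
  present <- as.logical(present)
  if (length(present) != k) stop("present mask length mismatch", call. = FALSE)
  if (!any(present)) stop("specimen ", specimen_id,
                          " has no present landmarks", call. = FALSE)
  if (any(!is.finite(coords[present, , drop = FALSE])))
    stop("non-finite coordinates at present landmarks for ", specimen_id,
         call. = FALSE)
  coords[!present, ] <- NA_real_
  if (is.null(imputed)) imputed <- rep(FALSE, k)
  if (!sex %in% c("F", "M", "U")) stop("sex must be F, M or U", call. = FALSE)
  structure(list(specimen_id = as.character(specimen_id), site = site,
                 sex = sex, coords = coords, present = present,
                 imputed = as.logical(imputed)),
            class = "specimen_record")
}

#' @export
print.specimen_record <- function(x, ...) {
  cat(sprintf("Specimen '%s' (site %s, sex %s): %d landmarks, %d missing, %d imputed\n",
              x$specimen_id, x$site, x$sex, nrow(x$coords),
              sum(!x$present), sum(x$imputed)))
  invisible(x)
}

n_missing <- function(record) sum(!record$present)

#' Attach site metadata and assemble a validated dataset
#'
#' Joins specimen records to a site table (columns `site`, `diet_group`,
#' `latitude`, `longitude`) and validates against the landmark-set
#' specification. Diet groups must be one of the five regional codes
#' HOK, NEH, CCH, ICH, SWJ. Site matching is case-sensitive and exact.
#'
#' @param records list of `specimen_record`s.
#' @param sites_table data frame of site metadata.
#' @param spec the `landmark_set` the records were digitised under.
#' @return an object of class `annotated_dataset`.
#' @export
attach_metadata <- function(records, sites_table, spec) {
  stopifnot(inherits(spec, "landmark_set"))
  if (inherits(records, "specimen_record")) records <- list(records)
  sites <- as.data.frame(sites_table, stringsAsFactors = FALSE)
  need <- c("site", "diet_group", "latitude", "longitude")
  if (!all(need %in% names(sites)))
    stop("sites_table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sites$site))
    stop("duplicate sites in sites_table", call. = FALSE)
  sites$diet_group <- toupper(trimws(sites$diet_group))
  bad <- setdiff(unique(sites$diet_group), diet_groups())
  if (length(bad))
    stop("diet group(s) outside the five regional codes: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(abs(sites$latitude) > 90) || any(abs(sites$longitude) > 180))
    stop("site coordinates outside valid decimal-degree range", call. = FALSE)
  k <- n_landmarks(spec)
  for (r in records) {
    if (!inherits(r, "specimen_record"))
      stop("records must be specimen_record objects", call. = FALSE)
    if (nrow(r$coords) != k)
      stop(sprintf("specimen %s has %d landmarks; set '%s' declares %d",
                   r$specimen_id, nrow(r$coords), spec$set_id, k),
           call. = FALSE)
    if (!r$site %in% sites$site)
      stop("unknown site '", r$site, "' for specimen ", r$specimen_id,
           call. = FALSE)
  }
  structure(list(spec = spec, specimens = records,
                 sites = sites[, need, drop = FALSE]),
            class = "annotated_dataset")
}

#' Five regional diet-group codes
#' @return character vector `c("HOK","NEH","CCH","ICH","SWJ")`.
#' @export
diet_groups <- function() c("HOK", "NEH", "CCH", "ICH", "SWJ")

#' @export
print.annotated_dataset <- function(x, ...) {
  cat(sprintf("Annotated dataset: %d specimens, %d sites, landmark set '%s' (%d points)\n",
              length(x$specimens), nrow(x$sites), x$spec$set_id,
              n_landmarks(x$spec)))
  invisible(x)
}

# diet group of each specimen, via its site
specimen_diet <- function(dataset) {
  dg <- dataset$sites$diet_group[match(vapply(dataset$specimens, `[[`, "",
                                              "site"), dataset$sites$site)]
  dg
}

#' Stack a complete dataset into a k x 3 x n coordinate array
#'
#' @param dataset an `annotated_dataset` whose specimens are all complete
#'   (see [subset_complete()]).
#' @return k x 3 x n array (landmarks x axes x specimens).
#' @export
dataset_array <- function(dataset) {
  ok <- vapply(dataset$specimens, function(r) all(r$present), TRUE)
  if (!all(ok)) stop("dataset contains incomplete specimens; run ",
                     "subset_complete() first", call. = FALSE)
  k <- n_landmarks(dataset$spec)
  arr <- array(NA_real_, c(k, 3, length(dataset$specimens)),
               dimnames = list(dataset$spec$definitions$name, c("x", "y", "z"),
                               vapply(dataset$specimens, `[[`, "", "specimen_id")))
  for (i in seq_along(dataset$specimens)) arr[, , i] <- dataset$specimens[[i]]$coords
  arr
}
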