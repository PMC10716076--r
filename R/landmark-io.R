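#' Read a TPS landmark file
#'
#' Supports the two common 3D dialects: blocks headed `LM=<k>` (rows with
#' three numbers are treated as 3D) or `LM3=<k>`, with `ID=` lines and an
#' optional `SCALE=` line whose value multiplies the coordinates. TPS has no
#' standard missing-data encoding; coordinates equal to `missing_value`
#' (all three of a row) are flagged absent.
#'
#' @param path file path.
#' @param missing_value sentinel marking a missing landmark (default -9999).
#' @return list of [specimen_record()]s.
#' @export
read_tps <- function(path, missing_value = -9999) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  records <- list()
  i <- 1L
  block <- 0L
  expected_k <- NULL
  while (i <= length(lines)) {
    ln <- lines[i]
    if (ln == "") { i <- i + 1L; next }
    m <- regmatches(ln, regexec("^LM3?=([0-9]+)$", ln, ignore.case = TRUE))[[1]]
    if (length(m) == 0)
      stop("expected LM=/LM3= header at line ", i, ", got: ", ln, call. = FALSE)
    k <- as.integer(m[2])
    block <- block + 1L
    coords <- matrix(NA_real_, k, 3)
    for (j in seq_len(k)) {
      i <- i + 1L
      if (i > length(lines)) stop("unexpected end of file in block ", block,
                                  call. = FALSE)
      vals <- suppressWarnings(as.numeric(strsplit(lines[i], "[ \t,]+")[[1]]))
      if (length(vals) != 3 || any(is.na(vals)))
        stop("non-numeric or non-3D coordinate row at line ", i, call. = FALSE)
      coords[j, ] <- vals
    }
    id <- paste0("specimen_", block)
    scale <- 1
    repeat {
      if (i + 1L > length(lines)) break
      nxt <- lines[i + 1L]
      if (grepl("^ID=", nxt, ignore.case = TRUE)) {
        id <- sub("^ID=", "", nxt, ignore.case = TRUE); i <- i + 1L
      } else if (grepl("^SCALE=", nxt, ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE=", "", nxt, ignore.case = TRUE))
        if (is.na(scale)) stop("non-numeric SCALE= at line ", i + 1L,
                               call. = FALSE)
        i <- i + 1L
      } else if (grepl("^IMAGE=", nxt, ignore.case = TRUE)) {
        i <- i + 1L  # tolerated, ignored
      } else break
    }
    present <- !apply(coords == missing_value, 1, all)
    coords <- coords * scale
    coords[!present, ] <- NA_real_
    if (!is.null(expected_k) && k != expected_k)
      stop(sprintf("inconsistent landmark count for specimen %s (%d, expected %d)",
                   id, k, expected_k), call. = FALSE)
    expected_k <- k
    records[[length(records) + 1L]] <- specimen_record(id, coords, present)
    i <- i + 1L
  }
  records
}

#' Write specimen records to a TPS file
#'
#' @param records list of `specimen_record`s.
#' @inheritParams read_tps
#' @export
write_tps <- function(records, path, missing_value = -9999) {
  if (inherits(records, "specimen_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    co <- r$coords
    co[!r$present, ] <- missing_value
    writeLines(sprintf("LM3=%d", nrow(co)), con)
    writeLines(apply(co, 1, function(p)
      paste(formatC(p, format = "g", digits = 15), collapse = " ")), con)
    writeLines(paste0("ID=", r$specimen_id), con)
  }
  invisible(path)
}

#' Read landmarks from CSV
#'
#' Long format has columns `specimen_id, landmark_index, x, y, z`; wide
#' format has `specimen_id` plus `lm<j>_x, lm<j>_y, lm<j>_z` triples.
#' Empty cells encode missing landmarks.
#'
#' @param path file path.
#' @param format `"long"` or `"wide"`.
#' @return list of [specimen_record()]s.
#' @export
read_landmarks_csv <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "long") {
    need <- c("specimen_id", "landmark_index", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop("long CSV needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    ids <- unique(df$specimen_id)
    k <- max(df$landmark_index)
    counts <- table(df$specimen_id)
    if (length(unique(counts)) > 1L)
      stop("inconsistent landmark count across specimens (first offender: ",
           names(counts)[counts != counts[1]][1], ")", call. = FALSE)
    lapply(ids, function(id) {
      sub <- df[df$specimen_id == id, ]
      coords <- matrix(NA_real_, k, 3)
      coords[sub$landmark_index, ] <- as.matrix(sub[, c("x", "y", "z")])
      specimen_record(id, coords)
    })
  } else {
    if (!"specimen_id" %in% names(df))
      stop("wide CSV needs a specimen_id column", call. = FALSE)
    xcols <- grep("^lm[0-9]+_x$", names(df), value = TRUE)
    k <- length(xcols)
    if (k == 0) stop("no lm<j>_x columns found", call. = FALSE)
    lapply(seq_len(nrow(df)), function(i) {
      coords <- matrix(NA_real_, k, 3)
      for (j in seq_len(k)) {
        coords[j, ] <- as.numeric(df[i, sprintf("lm%d_%s", j, c("x", "y", "z"))])
      }
      specimen_record(df$specimen_id[i], coords)
    })
  }
}

#' Write landmarks to CSV
#'
#' @inheritParams read_landmarks_csv
#' @param records list of `specimen_record`s.
#' @export
write_landmarks_csv <- function(records, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (inherits(records, "specimen_record")) records <- list(records)
  if (format == "long") {
    out <- do.call(rbind, lapply(records, function(r) {
      data.frame(specimen_id = r$specimen_id,
                 landmark_index = seq_len(nrow(r$coords)),
                 x = r$coords[, 1], y = r$coords[, 2], z = r$coords[, 3])
    }))
  } else {
    k <- nrow(records[[1]]$coords)
    out <- do.call(rbind, lapply(records, function(r) {
      row <- as.data.frame(as.list(c(t(r$coords))))
      names(row) <- as.vector(t(outer(seq_len(k), c("x", "y", "z"),
                                      function(j, a) sprintf("lm%d_%s", j, a))))
      cbind(data.frame(specimen_id = r$specimen_id), row)
    }))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a site metadata table
#'
#' Expects columns `site`, `diet_group`, and latitude/longitude in decimal
#' degrees (`latitude`/`longitude`, or `lat`/`lon`). Extra columns (such as
#' per-site sample sizes) are kept.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_site_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(df)
  nm[nm == "lat"] <- "latitude"; nm[nm == "lon"] <- "longitude"
  names(df) <- nm
  need <- c("site", "diet_group", "latitude", "longitude")
  if (!all(need %in% names(df)))
    stop("site table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a specimen metadata table (`specimen_id`, `site`, `sex`) and apply it
#' to records
#'
#' @param records list of `specimen_record`s.
#' @param path CSV path.
#' @return the records with site/sex filled in.
#' @export
apply_specimen_table <- function(records, path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "site", "sex")
  if (!all(need %in% names(df)))
    stop("specimen table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(records, function(r) {
    i <- match(r$specimen_id, df$specimen_id)
    if (is.na(i)) stop("specimen ", r$specimen_id,
                       " not in metadata table", call. = FALSE)
    r$site <- df$site[i]
    r$sex <- df$sex[i]
    if (!r$sex %in% c("F", "M", "U"))
      stop("sex must be F, M or U for ", r$specimen_id, call. = FALSE)
    r
  })
}
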