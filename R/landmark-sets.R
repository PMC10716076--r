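#' Landmark-set specifications
#'
#' A landmark set describes the named 3D points digitised on each cranium:
#' their order, their laterality (midline, left, or right of the sagittal
#' plane), the bilateral pairing used for mirror imputation, and whether a
#' point is a true landmark or a semilandmark (semilandmarks contribute to
#' muscle centroid sizes only and never enter shape analyses).
#'
#' Five sets are built in, mirroring the usual subdivision of a fragmentary
#' cranial sample: `craniofacial` (37 landmarks, whole cranium),
#' `facial` (22 landmarks, a named subset of the craniofacial set),
#' `neurocranial` (9 landmarks), `temporalis` (6 landmarks around the
#' temporalis muscle region), and `biteforce` (12 landmarks plus 14
#' semilandmarks for muscle size, plus the temporomandibular joint and the
#' M2 bite point used as lever/moment-arm endpoints).
#'
#' @param set_id one of `"craniofacial"`, `"facial"`, `"neurocranial"`,
#'   `"temporalis"`, `"biteforce"`.
#' @param definitions data frame with columns `name`, `index`, `laterality`
#'   (`"midline"`, `"left"`, `"right"`), `partner` (index of the bilateral
#'   partner, `NA` for midline or unpaired lateral points) and `role`
#'   (`"shape"` or `"semilandmark"`).
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(set_id, definitions) {
  set_id <- match.arg(set_id, c("craniofacial", "facial", "neurocranial",
                                "temporalis", "biteforce"))
  d <- as.data.frame(definitions, stringsAsFactors = FALSE)
  need <- c("name", "index", "laterality", "partner", "role")
  if (!all(need %in% names(d)))
    stop("definitions must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d <- d[order(d$index), need]
  k <- nrow(d)
  if (!identical(as.integer(d$index), seq_len(k)))
    stop("landmark indices must be unique and contiguous from 1", call. = FALSE)
  if (anyDuplicated(d$name)) stop("landmark names must be unique", call. = FALSE)
  if (!all(d$laterality %in% c("midline", "left", "right")))
    stop("laterality must be midline, left or right", call. = FALSE)
  if (!all(d$role %in% c("shape", "semilandmark")))
    stop("role must be shape or semilandmark", call. = FALSE)
  if (any(d$laterality == "midline" & !is.na(d$partner)))
    stop("midline landmarks cannot have a bilateral partner", call. = FALSE)
  paired <- which(!is.na(d$partner))
  for (i in paired) {
    j <- d$partner[i]
    if (!(j %in% seq_len(k)) || j == i)
      stop("invalid partner index for landmark ", d$name[i], call. = FALSE)
    if (is.na(d$partner[j]) || d$partner[j] != i)
      stop("bilateral partnering must be a symmetric involution (",
           d$name[i], ")", call. = FALSE)
    if (d$laterality[i] == d$laterality[j] ||
        any(d$laterality[c(i, j)] == "midline"))
      stop("partners must be one left and one right landmark (",
           d$name[i], ")", call. = FALSE)
  }
  structure(list(set_id = set_id, definitions = d), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  d <- x$definitions
  cat(sprintf("Landmark set '%s': %d points (%d midline, %d paired, %d semilandmarks)\n",
              x$set_id, nrow(d), sum(d$laterality == "midline"),
              sum(!is.na(d$partner)), sum(d$role == "semilandmark")))
  invisible(x)
}

n_landmarks <- function(spec) nrow(spec$definitions)

# ---- built-in anatomy -------------------------------------------------------

# master coordinate table (mm) for the template skull; x is lateral (right
# positive), y anterior, z superior; midline points sit on x = 0
.midline_coords <- matrix(c(
  0,  95,  25,   # glabella
  0,  93,  15,   # nasion
  0,  88, -15,   # nasospinale
  0,  87, -22,   # subspinale
  0,  86, -30,   # prosthion
  0,  45, -38,   # staphylion
  0,  10, -40,   # basion
  0, -25, -35,   # opisthion
  0, -78,  -5,   # inion
  0, -70,  40,   # lambda
  0,  10,  70,   # bregma
  0,  90,  35,   # ophryon
  0, -20,  72    # vertex
), ncol = 3, byrow = TRUE,
dimnames = list(c("glabella", "nasion", "nasospinale", "subspinale",
                  "prosthion", "staphylion", "basion", "opisthion", "inion",
                  "lambda", "bregma", "ophryon", "vertex"), c("x", "y", "z")))

.lateral_coords <- matrix(c(
  50, -60,   5,  # asterion
  60, -15, -20,  # porion
  58,  35,  30,  # pterion_posterior
  52,  65,  35,  # frontotemporale
  55,  40,  55,  # stephanion
  45,  70, -18,  # zygomaxillare
  40,  78,   5,  # zygoorbitale
  48,  80,  20,  # frontomalare_temporale
  15,  90,  12,  # dacryon
  68, -20,  30,  # euryon
  55, -25, -35,  # mastoidale
  12,  90, -12,  # alare
  30,  85,   8,  # ethmion
  62,  20,  10,  # MW1
  64,  -5,  15   # MW2
), ncol = 3, byrow = TRUE,
dimnames = list(c("asterion", "porion", "pterion_posterior", "frontotemporale",
                  "stephanion", "zygomaxillare", "zygoorbitale",
                  "frontomalare_temporale", "dacryon", "euryon", "mastoidale",
                  "alare", "ethmion", "MW1", "MW2"), c("x", "y", "z")))

.craniofacial_pairs <- c("asterion", "porion", "pterion_posterior",
                         "frontotemporale", "stephanion", "zygomaxillare",
                         "zygoorbitale", "frontomalare_temporale", "dacryon",
                         "euryon", "mastoidale", "alare")

.facial_midline <- c("glabella", "nasion", "nasospinale", "subspinale",
                     "prosthion", "staphylion")
.facial_pairs <- c("zygomaxillare", "zygoorbitale", "frontomalare_temporale",
                   "dacryon", "alare", "frontotemporale", "stephanion", "porion")

bilateral_defs <- function(midline, pairs) {
  nm <- c(midline, as.vector(rbind(paste0(pairs, "_R"), paste0(pairs, "_L"))))
  k <- length(nm)
  lat <- c(rep("midline", length(midline)), rep(c("right", "left"), length(pairs)))
  partner <- rep(NA_integer_, k)
  for (p in seq_along(pairs)) {
    i <- length(midline) + 2 * p - 1
    partner[i] <- i + 1L
    partner[i + 1] <- i
  }
  data.frame(name = nm, index = seq_len(k), laterality = lat,
             partner = partner, role = "shape", stringsAsFactors = FALSE)
}

# bite-force point order: ring of 18 temporalis points (7 landmarks,
# 11 semilandmarks), 8 masseter points (5 landmarks, 3 semilandmarks),
# then TMJ and the M2 bite point
.biteforce_layout <- local({
  ring_order <- c(2L, 16L, 3L, 17L, 4L, 18L, 9L, 19L, 10L, 20L, 11L, 21L,
                  12L, 22L, 23L, 24L, 25L, 26L)
  arch_order <- c(1L, 13L, 5L, 14L, 6L, 15L, 7L, 8L)
  coords <- matrix(NA_real_, 28, 3)
  theta <- (seq_along(ring_order) - 1) * 20 * pi / 180
  coords[ring_order, ] <- cbind(58, 20 + 28 * cos(theta), 30 + 28 * sin(theta))
  t8 <- seq(0, 7)
  coords[arch_order, ] <- cbind(45 + 1.4 * t8, 65 - 10 * t8, -15 - 0.6 * t8)
  coords[27, ] <- c(55, -12, -25)  # TMJ
  coords[28, ] <- c(30,  55, -32)  # M2 bite point
  colnames(coords) <- c("x", "y", "z")
  role <- rep("shape", 28)
  role[13:26] <- "semilandmark"
  nm <- paste0("bf", 1:28)
  nm[27] <- "TMJ"; nm[28] <- "M2"
  list(coords = coords,
       defs = data.frame(name = nm, index = 1:28, laterality = "right",
                         partner = NA_integer_, role = role,
                         stringsAsFactors = FALSE))
})

#' Built-in landmark sets
#'
#' @param set_id which set to return (see [landmark_set()]).
#' @return a `landmark_set` object.
#' @export
builtin_landmark_set <- function(set_id = c("craniofacial", "facial",
                                            "neurocranial", "temporalis",
                                            "biteforce")) {
  set_id <- match.arg(set_id)
  defs <- switch(set_id,
    craniofacial = bilateral_defs(rownames(.midline_coords), .craniofacial_pairs),
    facial = bilateral_defs(.facial_midline, .facial_pairs),
    neurocranial = data.frame(
      name = c("glabella", "bregma", "lambda", "inion", "opisthion",
               "pterion_posterior_R", "porion_R", "asterion_R",
               "frontotemporale_R"),
      index = 1:9,
      laterality = c(rep("midline", 5), rep("right", 4)),
      partner = NA_integer_, role = "shape", stringsAsFactors = FALSE),
    temporalis = data.frame(
      name = c("frontotemporale_R", "stephanion_R", "ethmion_R",
               "zygomaxillare_R", "MW1_R", "MW2_R"),
      index = 1:6, laterality = "right", partner = NA_integer_,
      role = "shape", stringsAsFactors = FALSE),
    biteforce = .biteforce_layout$defs)
  landmark_set(set_id, defs)
}

#' Symmetric template skull configuration for a landmark set
#'
#' Returns an idealised, exactly bilaterally symmetric configuration in mm:
#' midline landmarks lie on the x = 0 plane and bilateral pairs are exact
#' mirror images in x. Used as the ground-truth shape by the synthetic-data
#' generator and as the reference in symmetry-based tests.
#'
#' @param spec a `landmark_set`.
#' @return a k x 3 matrix of coordinates (rows named by landmark).
#' @export
make_template_skull <- function(spec) {
  stopifnot(inherits(spec, "landmark_set"))
  d <- spec$definitions
  if (spec$set_id == "biteforce") {
    out <- .biteforce_layout$coords
    rownames(out) <- d$name
    return(out)
  }
  base <- rbind(.midline_coords, .lateral_coords)
  out <- matrix(NA_real_, nrow(d), 3, dimnames = list(d$name, c("x", "y", "z")))
  for (i in seq_len(nrow(d))) {
    nm <- d$name[i]
    side <- 1
    root <- nm
    if (grepl("_R$", nm)) root <- sub("_R$", "", nm)
    if (grepl("_L$", nm)) { root <- sub("_L$", "", nm); side <- -1 }
    if (!root %in% rownames(base))
      stop("no template coordinate for landmark ", nm, call. = FALSE)
    p <- base[root, ]
    out[i, ] <- c(side * p["x"], p["y"], p["z"])
  }
  out
}
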