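# shared fixture builders; everything is generated in code at test time

# a small bilaterally symmetric landmark set: 4 midline + 3 pairs (10 points)
toy_spec <- function() {
  landmark_set("craniofacial", data.frame(
    name = c("m1", "m2", "m3", "m4",
             "p1_R", "p1_L", "p2_R", "p2_L", "p3_R", "p3_L"),
    index = 1:10,
    laterality = c(rep("midline", 4), rep(c("right", "left"), 3)),
    partner = c(NA, NA, NA, NA, 6L, 5L, 8L, 7L, 10L, 9L),
    role = "shape", stringsAsFactors = FALSE))
}

toy_template <- function() {
  rbind(m1 = c(0, 0, 0), m2 = c(0, 20, 0), m3 = c(0, 40, 10),
        m4 = c(0, 20, 30),
        p1_R = c(15, 5, 5),  p1_L = c(-15, 5, 5),
        p2_R = c(20, 25, 10), p2_L = c(-20, 25, 10),
        p3_R = c(12, 35, 25), p3_L = c(-12, 35, 25))
}

# random proper rotation from the current RNG stream
rand_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotation_about <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

# record from a configuration with optional deleted landmark indices
as_record <- function(coords, delete = integer(), id = "s1", site = NA, sex = "U") {
  present <- rep(TRUE, nrow(coords))
  present[delete] <- FALSE
  co <- coords
  co[delete, ] <- NA_real_
  specimen_record(id, co, present, site = site, sex = sex)
}

# exhaustive double-sum Moran's I oracle
morans_i_oracle <- function(x, w) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
  (n / sum(w)) * num / sum((x - xb)^2)
}

# two-group tangent-level dataset with known mean offset along `dir`
offset_groups <- function(n_per = 15, p = 20, delta = 0.05, noise = 0.01) {
  dir <- c(1, rep(0, p - 1))
  Y1 <- matrix(rnorm(n_per * p, 0, noise), n_per)
  Y2 <- matrix(rnorm(n_per * p, 0, noise), n_per)
  Y2 <- sweep(Y2, 2, delta * dir, `+`)
  list(tangent = rbind(Y1, Y2),
       labels = rep(c("A", "B"), each = n_per))
}
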