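test_that("haversine distances match closed forms", {
  sites <- data.frame(site = c("a", "b", "c", "d"),
                      latitude = c(0, 0, 0, 10),
                      longitude = c(0, 1, 180, 20))
  m <- site_distance_matrix(sites)
  expect_equal(diag(m), rep(0, 4), ignore_attr = TRUE)
  expect_identical(m, t(m))
  expect_equal(m["a", "b"], 6371.0088 * pi / 180, tolerance = 1e-3 / 111)
  expect_equal(m["a", "c"], pi * 6371.0088, tolerance = 0.1 / 20015)
  expect_error(site_distance_matrix(data.frame(site = "x", latitude = 91,
                                               longitude = 0)), "coordinates")
})

test_that("distance classes partition all site pairs into 100-km bins", {
  m <- jomon_site_distances()
  dc <- distance_classes(m, 100)
  expect_equal(nrow(dc), 17L)
  expect_equal(sum(dc$n_pairs), 16 * 15 / 2)
  expect_true(all(dc$upper_km - dc$lower_km == 100))
  with_data <- !is.na(dc$mean_distance_km)
  expect_true(all(dc$mean_distance_km[with_data] >= dc$lower_km[with_data] &
                    dc$mean_distance_km[with_data] < dc$upper_km[with_data]))
  # class 1 holds the closest pairs: Yoshigo-Ikawazu and Yamaga-Einomaru
  p1 <- attr(dc, "pairs")[[1]]
  sites <- attr(dc, "sites")
  pair_names <- apply(p1, 1, function(ij)
    paste(sort(sites[ij]), collapse = "-"))
  expect_true("Ikawazu-Yoshigo" %in% pair_names)
  expect_true("Einomaru-Yamaga" %in% pair_names)
})

test_that("three sites at distances 50/150/250 fall into classes 1-3", {
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m[1, 2] <- m[2, 1] <- 50
  m[2, 3] <- m[3, 2] <- 150
  m[1, 3] <- m[3, 1] <- 250
  dc <- distance_classes(m, 100)
  expect_equal(dc$n_pairs, c(1L, 1L, 1L))
})

test_that("Moran's I equals the brute-force double sum for all n <= 6", {
  set.seed(101)
  for (n in 2:6) {
    for (rep in 1:10) {
      x <- rnorm(n)
      w <- matrix(rbinom(n * n, 1, 0.6), n)
      w[lower.tri(w)] <- t(w)[lower.tri(w)]
      diag(w) <- 0
      if (sum(w) == 0) next
      expect_equal(morans_i(x, w), morans_i_oracle(x, w), tolerance = 1e-12)
    }
  }
  # n = 2 algebraic identity
  expect_equal(morans_i(c(0.3, 9.1), matrix(c(0, 1, 1, 0), 2)), -1,
               tolerance = 1e-12)
  expect_error(morans_i(rep(1, 4), matrix(1, 4, 4) - diag(4)), "variance")
  expect_true(is.na(morans_i(rnorm(4), matrix(0, 4, 4))))
})

test_that("Moran's I agrees with ape on an equal-row-sum weight structure", {
  skip_if_not_installed("ape")
  set.seed(102)
  n <- 8
  w <- matrix(0, n, n)  # ring adjacency: every row sums to 2
  for (i in seq_len(n)) {
    j <- i %% n + 1
    w[i, j] <- w[j, i] <- 1
  }
  x <- rnorm(n)
  expect_equal(morans_i(x, w), ape::Moran.I(x, w)$observed, tolerance = 1e-9)
})

test_that("permutation null of Moran's I centres on -1/(n-1)", {
  set.seed(103)
  n <- 10
  w <- matrix(rbinom(n * n, 1, 0.4), n)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  diag(w) <- 0
  x <- rnorm(n)
  draws <- vapply(1:2000, function(b) morans_i(sample(x), w), 1.0)
  se <- sd(draws) / sqrt(2000)
  expect_lt(abs(mean(draws) - (-1 / (n - 1))), 3 * se)
})

test_that("correlograms detect an isolation-by-distance cline", {
  # 8 sites on a 700-km transect with value = position along the transect
  # (a latitude proxy) plus noise: positive I in class 1, negative in the
  # most distant class
  sites <- transect_sites(8, 700)
  dm <- site_distance_matrix(sites)
  arc <- dm[1, ]
  hits <- vapply(1:20, function(s) {
    set.seed(300 + s)
    v <- arc / 700 + rnorm(8, 0, 0.1)
    cg <- correlogram(v, dm, 100, n_perm = 49, seed = s)
    defined <- which(cg$defined)
    cg$morans_i[1] > 0 && cg$morans_i[max(defined)] < 0
  }, TRUE)
  expect_gte(sum(hits), 19)
})

test_that("classes joined only through data-less sites are flagged undefined", {
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d <- c(10, 120, 130, 110, 140, 250)  # ab, ac, ad, bc, bd, cd
  m[upper.tri(m)] <- d
  m <- m + t(m)
  v <- c(1.2, -0.5, 0.8, 0.1)
  cg0 <- correlogram(v, m, 100, n_perm = 49, seed = 1)
  expect_true(all(cg0$defined[c(1, 2, 3)]))
  v[4] <- NA  # drop site d: class 3 (cd = 250) only joins pairs with d
  cg1 <- correlogram(v, m, 100, n_perm = 49, seed = 1)
  expect_false(cg1$defined[3])
  expect_true(is.na(cg1$p_perm[3]))
  expect_true(is.na(cg1$morans_i[3]))
  # class 2 loses the ad/bd pairs but keeps ac/bc
  expect_true(cg1$defined[2])
  expect_equal(cg1$n_pairs[2], 2L)
})

test_that("site summaries average specimen values per site", {
  set.seed(104)
  sites <- transect_sites(4, 300, n_per_site = 3)
  sim <- simulation_spec(sites = sites, set_id = "neurocranial",
                         group_effect_norm = 0, missing_rate = 0, seed = 3)
  d <- generate_dataset(sim)$dataset
  g <- gpa(dataset_array(d))
  summ <- site_summaries(d, g)
  expect_equal(nrow(summ), 4L)
  expect_equal(summ$n, rep(3L, 4))
  site_of <- vapply(d$specimens, `[[`, "", "site")
  i <- which(site_of == summ$site[2])
  expect_equal(summ$csize[2], mean(g$csize[i]), tolerance = 1e-12)
  pc <- shape_pca(g$tangent)
  expect_equal(summ$PC1[2], mean(pc$scores[i, 1]), tolerance = 1e-12)

  # one-specimen site: summary equals that specimen's values
  sites1 <- sites; sites1$n <- c(1, 3, 3, 3)
  d1 <- generate_dataset(simulation_spec(sites = sites1,
                                         set_id = "neurocranial",
                                         missing_rate = 0, seed = 4))$dataset
  g1 <- gpa(dataset_array(d1))
  s1 <- site_summaries(d1, g1)
  expect_equal(s1$csize[1], g1$csize[1], tolerance = 1e-12)
})

test_that("site-level PC1 offsets are recovered from a cline simulation", {
  set.seed(105)
  sites <- transect_sites(4, 600, n_per_site = 10)
  sim <- simulation_spec(sites = sites, set_id = "neurocranial",
                         group_effect_norm = 0, allometry_frac = 0,
                         spatial_cline = 1e-4, noise_sd = 0.5,
                         missing_rate = 0, seed = 9)
  out <- generate_dataset(sim)
  g <- gpa(dataset_array(out$dataset))
  summ <- site_summaries(out$dataset, g)
  # PC1 site means should be collinear with the injected cline coordinate
  r <- abs(cor(summ$PC1, out$truth$site_expect$cline_component))
  expect_gt(r, 0.95)
})
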