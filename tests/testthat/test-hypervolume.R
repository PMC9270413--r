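test_that("bandwidth rules follow their closed forms and scale equivariance", {
  set.seed(1)
  X <- matrix(rnorm(500), ncol = 5)
  sds <- apply(X, 2, sd)
  expect_equal(estimate_bandwidth(X), 1.06 * sds * 100^(-0.2))
  expect_equal(estimate_bandwidth(X, rule = "multivariate"),
               (4 / 7)^(1 / 9) * 100^(-1 / 9) * sds)
  expect_equal(estimate_bandwidth(2 * X), 2 * estimate_bandwidth(X))
  expect_error(estimate_bandwidth(X[1, , drop = FALSE]), "at least 2")
  Xc <- X; Xc[, 3] <- 1
  expect_error(estimate_bandwidth(Xc), "constant axis")
})

test_that("density_at matches the single-kernel closed form and far points excluded", {
  x0 <- c(0.2, 0.4, 0.1, 0.05, 0.25)
  X <- rbind(x0, x0 + 1e-3, x0 - 1e-3, x0 + 2e-3, x0 - 2e-3)
  colnames(X) <- paste0("a", 1:5)
  b <- rep(0.1, 5)
  hv <- build_hypervolume(X, bandwidth = b, n_samples = 2000, seed = 2)
  q <- matrix(c(x0 + 0.05, x0 + 100), nrow = 2, byrow = TRUE)
  d <- density_at(hv, q)
  manual <- mean(sapply(seq_len(5), function(j) prod(dnorm(q[1, ], X[j, ], b))))
  expect_equal(d$density[1], manual, tolerance = 1e-12)
  expect_equal(d$density[2], 0)
  expect_false(d$included[2])
  # a retained sample is self-consistently included
  self <- density_at(hv, hv$samples[1, , drop = FALSE])
  expect_true(self$included)
  expect_error(density_at(hv, matrix(0, 1, 3)), "axes")
})

test_that("volume doubles by 2^d when axis units double", {
  set.seed(3)
  X <- matrix(rnorm(600), ncol = 5)
  b <- rep(0.5, 5)
  v1 <- build_hypervolume(X, bandwidth = b, n_samples = 15000, seed = 4)$volume
  v2 <- build_hypervolume(2 * X, bandwidth = 2 * b, n_samples = 15000, seed = 4)$volume
  expect_equal(v2 / v1, 2^5, tolerance = 0.05)
})

test_that("volume estimator tightens with more samples and respects monotonicity", {
  set.seed(5)
  X <- matrix(rnorm(100 * 5), ncol = 5)
  b <- rep(0.8, 5)
  vols <- function(ns) sapply(1:12, function(s)
    build_hypervolume(X, bandwidth = b, n_samples = ns, seed = s)$volume)
  v_small <- vols(2000)
  v_large <- vols(16000)
  expect_lt(sd(v_large), sd(v_small))
  # monotone in mass quantile (within Monte-Carlo tolerance)
  v90 <- build_hypervolume(X, bandwidth = b, mass_quantile = 0.90,
                           n_samples = 10000, seed = 1)$volume
  v99 <- build_hypervolume(X, bandwidth = b, mass_quantile = 0.99,
                           n_samples = 10000, seed = 1)$volume
  expect_gt(v99, v90)
  # monotone in bandwidth
  v_wide <- build_hypervolume(X, bandwidth = b * 1.5, n_samples = 10000,
                              seed = 1)$volume
  v_base <- build_hypervolume(X, bandwidth = b, n_samples = 10000,
                              seed = 1)$volume
  expect_gt(v_wide, v_base)
  # inclusion and volume share one threshold
  hv <- build_hypervolume(X, bandwidth = b, n_samples = 5000, seed = 9)
  expect_true(all(hv$sample_density >= hv$density_threshold))
  expect_equal(hv$volume, sum(1 / hv$sample_density) / hv$n_samples)
})

test_that("hypervolume construction enforces the occurrence and axis filters", {
  X <- matrix(rnorm(20), ncol = 5)
  expect_error(build_hypervolume(X), "fewer than 5 occurrence")
  X2 <- matrix(rnorm(40), ncol = 4)
  expect_error(build_hypervolume(X2), "fewer than 5 axes")
  X3 <- matrix(rnorm(50), ncol = 5)
  expect_error(build_hypervolume(X3, bandwidth = c(1, 1, 1, 1, 0)), "bandwidth")
  expect_warning(build_hypervolume(X3, bandwidth = rep(1, 5), n_samples = 500,
                                   seed = 1), "unstable")
})

test_that("hypervolume JSON cache round-trips volume and inclusion", {
  set.seed(19)
  X <- matrix(rnorm(40 * 5), ncol = 5)
  hv <- build_hypervolume(X, bandwidth = rep(0.7, 5), n_samples = 2000, seed = 6)
  f <- withr::local_tempfile(fileext = ".json")
  write_hypervolume(hv, f)
  back <- read_hypervolume(f)
  expect_equal(back$volume, hv$volume)
  expect_equal(back$bandwidth, hv$bandwidth)
  q <- matrix(rnorm(10 * 5), ncol = 5)
  expect_equal(density_at(back, q), density_at(hv, q))
})

test_that("species units apply occurrence, axis and pairing filters", {
  sites <- generate_sites(240, confounding_strength = 0, seed = 10)
  hab <- grep("^habitat_", names(sites), value = TRUE)
  # species A occupies 10 sites per class in P1; species B only 4 protected
  occ <- dplyr::bind_rows(
    tibble::tibble(species_id = "A",
                   site_id = sites$site_id[sites$protected][1:10]),
    tibble::tibble(species_id = "A",
                   site_id = sites$site_id[!sites$protected][1:10]),
    tibble::tibble(species_id = "B",
                   site_id = sites$site_id[sites$protected][1:4]),
    tibble::tibble(species_id = "B",
                   site_id = sites$site_id[!sites$protected][1:10])
  )
  # restrict to one period so counts are controlled
  sites$period <- "P1"
  units <- prepare_species_units(occ, sites)
  expect_true(all(units$pairs$species_id == "A"))
  expect_true(any(grepl("^B\\|", units$dropped$key)))
  expect_identical(
    units$dropped$reason[grepl("^B\\|P1\\|protected", units$dropped$key)],
    "fewer_than_min_occurrences"
  )
  # a unit whose occupied sites are constant on 3 axes falls under the axis filter
  sites2 <- sites
  sites2[sites2$protected, hab[1:3]] <- 0.0
  units2 <- prepare_species_units(
    dplyr::filter(occ, species_id == "A"), sites2)
  expect_identical(
    units2$dropped$reason[grepl("^A\\|P1\\|protected", units2$dropped$key)],
    "fewer_than_min_axes"
  )
})
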