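test_that("propensity model reduces to the protected fraction for constant covariates", {
  sites <- toy_sites(10)
  hab <- grep("^habitat_", names(sites), value = TRUE)
  sites[hab] <- lapply(sites[hab], function(x) rep(1 / 7, nrow(sites)))
  p <- suppressWarnings(fit_propensity(sites, hab))
  expect_equal(unname(as.numeric(p)), rep(mean(sites$protected), nrow(sites)))
})

test_that("propensity scores agree with a brute-force ML grid search", {
  set.seed(31)
  sites <- toy_sites(8)
  sites$habitat_coniferous <- c(0.9, 0.2, 0.3, 0.8, 0.7, 0.35, 0.4, 0.6)
  p <- fit_propensity(sites, "habitat_coniferous")
  beta <- grid_logistic(sites$habitat_coniferous, as.integer(sites$protected))
  oracle <- plogis(beta[1] + beta[2] * sites$habitat_coniferous)
  expect_equal(unname(as.numeric(p)), unname(oracle), tolerance = 1e-4)
})

test_that("propensity preconditions and separation handling", {
  sites <- toy_sites(8)
  sites$protected <- TRUE
  expect_error(fit_propensity(sites, "habitat_water"), "both protection classes")
  # perfectly separating covariate
  sep <- toy_sites(8)
  sep$habitat_water <- ifelse(sep$protected, 0.9, 0.1)
  expect_error(fit_propensity(sep, "habitat_water"), "separation")
  p <- fit_propensity(sep, "habitat_water", ridge = TRUE)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(p[sep$protected] > p[!sep$protected]))
})

test_that("mahalanobis distance matches the quadratic form and reduces to Euclid", {
  S <- matrix(c(2, 0.5, 0.3, 0.5, 1.5, 0.2, 0.3, 0.2, 1), 3, 3)
  x <- c(0.1, 0.5, 0.3); y <- c(0.4, 0.2, 0.9)
  manual <- sqrt(drop(t(x - y) %*% solve(S) %*% (x - y)))
  expect_equal(mahalanobis_distance(x, y, S), manual, tolerance = 1e-10)
  expect_equal(mahalanobis_distance(x, y, S), mahalanobis_distance(y, x, S))
  expect_equal(mahalanobis_distance(x, x, S), 0)
  expect_equal(mahalanobis_distance(x, y, diag(3)), sqrt(sum((x - y)^2)))
  sing <- matrix(1, 3, 3)
  expect_error(mahalanobis_distance(x, y, sing), "singular")
  expect_gt(mahalanobis_distance(x, y, sing, regularize = TRUE), 0)
})

test_that("a duplicated protected table matches perfectly at distance zero", {
  set.seed(33)
  prot <- toy_sites(6, seed = 60)
  prot$protected <- TRUE
  unprot <- prot
  unprot$protected <- FALSE
  unprot$site_id <- sub("T", "U", unprot$site_id)
  sites <- dplyr::bind_rows(prot, unprot)
  hab <- grep("^habitat_", names(sites), value = TRUE)
  res <- match_sites(sites, match_spec(hab, ridge = TRUE))
  expect_equal(res$match_rate, 1.0)
  expect_equal(max(res$pairs$distance), 0)
  expect_length(res$unmatched_protected, 0)
})

test_that("caliper excludes an isolated protected site", {
  sites <- toy_sites(12, seed = 61)
  hab <- grep("^habitat_", names(sites), value = TRUE)[1:3]
  res <- match_sites(sites, match_spec(hab, caliper_sd = 1e-6))
  expect_gt(length(res$unmatched_protected), 0)
  res_wide <- match_sites(sites, match_spec(hab, caliper_sd = 50))
  expect_lt(length(res_wide$unmatched_protected),
            length(sites$site_id[sites$protected]))
})

test_that("greedy pairing equals an independent reference implementation", {
  for (seed in c(71, 72, 73)) {
    sites <- dplyr::bind_rows(toy_sites(12, seed = seed),
                              dplyr::mutate(toy_sites(12, seed = seed + 100),
                                            site_id = sprintf("X%02d", 1:12),
                                            zone = "NB"))
    hab <- grep("^habitat_", names(sites), value = TRUE)[1:3]
    spec <- match_spec(hab, caliper_sd = 0.25)
    res <- match_sites(sites, spec)
    scores <- as.numeric(fit_propensity(sites, hab))
    ref <- greedy_match_reference(sites, scores, res$caliper)
    expect_identical(res$pairs$protected_site_id, ref[, 1])
    expect_identical(res$pairs$unprotected_site_id, ref[, 2])
  }
})

test_that("matching never reuses sites and respects exact strata", {
  sites <- generate_sites(600, confounding_strength = 1.5, seed = 80)
  hab <- grep("^habitat_", names(sites), value = TRUE)
  res <- match_sites(sites, match_spec(hab))
  ids <- c(res$pairs$protected_site_id, res$pairs$unprotected_site_id)
  expect_false(any(duplicated(ids)))
  joined <- res$pairs |>
    dplyr::left_join(sites, by = c(protected_site_id = "site_id")) |>
    dplyr::left_join(sites, by = c(unprotected_site_id = "site_id"),
                     suffix = c("_p", "_u"))
  expect_true(all(joined$zone_p == joined$zone_u))
  expect_true(all(joined$period_p == joined$period_u))
  # propensity-score balance never worsens after matching
  scores <- as.numeric(fit_propensity(sites, hab))
  den <- sqrt((var(scores[sites$protected]) + var(scores[!sites$protected])) / 2)
  smd_score <- function(d, sc) {
    (mean(sc[d$protected]) - mean(sc[!d$protected])) / den
  }
  after <- sites$site_id %in% ids
  expect_lte(abs(smd_score(sites[after, ], scores[after])),
             abs(smd_score(sites, scores)))
})

test_that("balance report improves the worst covariate on a confounded design", {
  sites <- generate_sites(1500, confounding_strength = 2, seed = 81)
  hab <- grep("^habitat_", names(sites), value = TRUE)
  res <- match_sites(sites, match_spec(hab))
  bal <- balance_report(sites, res)
  expect_lt(max(abs(bal$smd_after)), max(abs(bal$smd_before)))
  # SMD definition cross-check on one covariate
  cl <- hab[1]
  ps <- sqrt((var(sites[[cl]][sites$protected]) +
                var(sites[[cl]][!sites$protected])) / 2)
  manual <- (mean(sites[[cl]][sites$protected]) -
               mean(sites[[cl]][!sites$protected])) / ps
  expect_equal(bal$smd_before[bal$covariate == cl], manual)
  empty <- res; empty$pairs <- res$pairs[0, ]
  expect_error(balance_report(sites, empty), "no matched pairs")
})

test_that("mahalanobis matching runs and respects strata too", {
  sites <- generate_sites(400, confounding_strength = 1, seed = 82)
  hab <- grep("^habitat_", names(sites), value = TRUE)
  res <- match_sites(sites, match_spec(hab, method = "mahalanobis"))
  expect_gt(nrow(res$pairs), 0)
  expect_true(all(res$pairs$distance >= 0))
  ids <- c(res$pairs$protected_site_id, res$pairs$unprotected_site_id)
  expect_false(any(duplicated(ids)))
})
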