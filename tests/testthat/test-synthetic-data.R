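test_that("site generator is deterministic, stratified and simplex-valid", {
  s1 <- generate_sites(150, confounding_strength = 0.5, seed = 1)
  s2 <- generate_sites(150, confounding_strength = 0.5, seed = 1)
  expect_identical(s1, s2)
  hab <- grep("^habitat_", names(s1), value = TRUE)
  expect_length(hab, 7)
  expect_true(all(abs(rowSums(s1[hab]) - 1) < 1e-9))
  expect_true(all(as.matrix(s1[hab]) >= 0 & as.matrix(s1[hab]) <= 1))
  expect_true(all(s1$effort > 0))
  # both classes in every stratum
  strata <- dplyr::count(s1, zone, period, protected)
  expect_equal(nrow(strata), 3 * 4 * 2)
  expect_error(generate_sites(10), "at least 2 per")
})

test_that("zero confounding leaves habitat balanced; strong confounding does not", {
  s0 <- generate_sites(1000, confounding_strength = 0, seed = 2)
  hab <- grep("^habitat_", names(s0), value = TRUE)
  pvals <- vapply(hab, function(cl) {
    stats::wilcox.test(s0[[cl]][s0$protected], s0[[cl]][!s0$protected])$p.value
  }, numeric(1))
  expect_true(all(pvals > 0.01))

  s2 <- generate_sites(2000, confounding_strength = 2, seed = 7)
  smd <- vapply(hab, function(cl) {
    ps <- sqrt((var(s2[[cl]][s2$protected]) + var(s2[[cl]][!s2$protected])) / 2)
    abs(mean(s2[[cl]][s2$protected]) - mean(s2[[cl]][!s2$protected])) / ps
  }, numeric(1))
  expect_gt(max(smd), 0.25)
})

test_that("occurrence generator is seeded, period-consistent and flags sparse species", {
  sites <- generate_sites(600, seed = 3)
  specs <- hp_scenario_specs(n_per_class = 1, n_target = 50L, seed = 4)
  o1 <- suppressWarnings(generate_occurrences(sites, specs, seed = 5))
  o2 <- suppressWarnings(generate_occurrences(sites, specs, seed = 5))
  expect_identical(o1, o2)
  # occurrences carry the period of their site
  j <- dplyr::left_join(o1, sites, by = "site_id", suffix = c("", "_site"))
  expect_true(all(j$period == j$period_site))
  # empty spec list -> empty table
  empty <- generate_occurrences(sites, list(), seed = 5)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("species_id", "site_id", "period"))
  # a species with a tiny target is flagged as below the downstream filter
  sparse <- niche_spec("rare", rep(1 / 7, 7), n_target = 2L)
  expect_warning(generate_occurrences(sites, list(sparse), seed = 6),
                 "expected occurrence count < 5")
})

test_that("null niche spec gives protected and unprotected draws from one law", {
  sites <- generate_sites(2000, confounding_strength = 0, seed = 8)
  hab <- grep("^habitat_", names(sites), value = TRUE)
  ctr <- colMeans(as.matrix(sites[hab]))
  sp <- niche_spec("null_sp", ctr, niche_sd = rep(0.12, 7), n_target = 150L)
  occ <- suppressWarnings(generate_occurrences(sites, list(sp), seed = 9))
  occ_sites <- dplyr::inner_join(occ, sites, by = "site_id")
  pvals <- vapply(hab, function(cl) {
    stats::wilcox.test(occ_sites[[cl]][occ_sites$protected],
                       occ_sites[[cl]][!occ_sites$protected])$p.value
  }, numeric(1))
  expect_true(all(pvals > 0.005))
})

test_that("trait generator hits the requested mass-generation correlation", {
  traits <- generate_traits(sprintf("s%03d", 1:100), mass_gl_correlation = 0.75,
                            seed = 10)
  r <- cor(log(traits$body_mass), log(traits$generation_length))
  expect_lt(abs(r - 0.75), 0.1)
  expect_true(all(vapply(traits$habitat_shares,
                         function(x) abs(sum(x) - 1) < 1e-9, logical(1))))
  expect_true(all(traits$vert_diet_prop >= 0 & traits$vert_diet_prop <= 1))
  expect_identical(traits,
                   generate_traits(sprintf("s%03d", 1:100),
                                   mass_gl_correlation = 0.75, seed = 10))
  # all-zero effect configuration leaves a null latent effect
  expect_true(all(traits$trait_effect == 0))
  t2 <- generate_traits(sprintf("s%03d", 1:50),
                        effect_config = c(log_body_mass = 0.8), seed = 11)
  expect_gt(sd(t2$trait_effect), 0)
  expect_error(generate_traits(c("a", "a", "b")), "duplicat")
})

test_that("tree generator round-trips and controls the phylogenetic signal", {
  ids <- sprintf("sp%02d", 1:12)
  g <- generate_tree(ids, lambda_true = 0.5, seed = 12)
  expect_s3_class(g$tree, "phylo")
  expect_setequal(g$tree$tip.label, ids)
  rt <- parse_newick(g$newick)
  expect_equal(ape::write.tree(rt), ape::write.tree(g$tree))
  # unit depth after rescaling
  expect_equal(max(ape::node.depth.edgelength(g$tree)), 1)
  expect_error(generate_tree(c("a", "a", "b")), "duplicate")
  expect_error(generate_tree(c("a", "b")), "at least 3")

  # lambda_true = 0 -> species effects essentially uncorrelated across sibs
  set.seed(13)
  effs <- replicate(200, {
    gg <- generate_tree(ids, lambda_true = 0, seed = sample.int(1e6, 1))
    gg$effect
  })
  C <- cor(t(effs))
  off <- C[upper.tri(C)]
  expect_lt(max(abs(off)), 0.25)
  expect_lt(mean(abs(off)), 0.08)
})
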