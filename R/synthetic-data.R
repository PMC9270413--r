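#' Synthetic survey design and niche ground truth
#'
#' Generators for sites, species occurrences, traits and a phylogeny with a
#' known generative niche structure, so the whole matched-design niche
#' pipeline can be exercised against ground truth: every generator is a pure
#' function of its arguments including the seed, and the strength of the
#' protection-habitat confounding, of the niche shift/expansion, of the
#' trait effects, and of the phylogenetic signal are all explicit knobs.
#'
#' @name synthetic-data
NULL

habitat_classes <- function() {
  c("habitat_artificial", "habitat_agricultural", "habitat_broadleaf",
    "habitat_coniferous", "habitat_mixed_forest", "habitat_shrub_herb",
    "habitat_water")
}

default_zones <- function() c("HB_SB", "MB", "NB")
default_periods <- function() c("P1", "P2", "P3", "P4")

# Boreal-flavoured Dirichlet concentrations: coniferous forest dominates,
# artificial surfaces are rare.
default_alpha <- function() {
  stats::setNames(c(0.6, 1.5, 0.8, 4.5, 2.0, 1.6, 1.5), habitat_classes())
}

#' Generate a synthetic site table
#'
#' Draws `n_sites` survey units spread evenly over the zone x period strata.
#' Habitat compositions come from a Dirichlet law on the 7-class land-cover
#' simplex; protection is assigned by a logistic model whose slope on the
#' (standardized) habitat covariates is `confounding_strength`, so at 0 the
#' protected and unprotected habitat distributions coincide and at larger
#' values the matching stage faces genuine selection bias. Each stratum is
#' guaranteed to contain both protection classes (the most/least eligible
#' site is flipped if a class is missing). Survey effort is lognormal
#' kilometres of transect.
#'
#' @param n_sites Total number of sites; at least 2 per stratum.
#' @param zones,periods Factor levels of the exact-matching strata.
#' @param confounding_strength Non-negative slope of the protection model on
#'   habitat covariates.
#' @param protected_fraction Target marginal protection probability.
#' @param alpha Dirichlet concentration vector over the 7 habitat classes.
#' @param seed Integer seed.
#' @return A tibble: `site_id`, `zone`, `period`, `protected`, `effort` and
#'   the seven `habitat_*` proportion columns (each row sums to 1).
#' @export
generate_sites <- function(n_sites, zones = default_zones(),
                           periods = default_periods(),
                           confounding_strength = 0,
                           protected_fraction = 1 / 3,
                           alpha = default_alpha(), seed = 1L) {
  stopifnot(n_sites >= 2, confounding_strength >= 0,
            length(alpha) == 7, all(alpha > 0))
  n_strata <- length(zones) * length(periods)
  if (n_sites < 2 * n_strata) {
    stop("n_sites must be at least 2 per zone x period stratum (",
         2 * n_strata, ")", call. = FALSE)
  }
  old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)

  strata <- tidyr::expand_grid(zone = zones, period = periods)
  assign_idx <- rep(seq_len(n_strata), length.out = n_sites)
  H <- rdirichlet_mat(n_sites, alpha)
  colnames(H) <- habitat_classes()

  # direction of the protection bias: protected land richer in coniferous
  # forest and shrub, poorer in agricultural and artificial cover
  w <- stats::setNames(c(-1, -1, 0, 1, 0, 1, 0.5), habitat_classes())
  Hs <- scale(H)
  lp0 <- drop(Hs %*% w) / sqrt(sum(w^2))
  eta <- stats::qlogis(protected_fraction) + confounding_strength * lp0
  protected <- stats::runif(n_sites) < stats::plogis(eta)

  sites <- tibble::tibble(
    site_id = sprintf("S%04d", seq_len(n_sites)),
    zone = strata$zone[assign_idx],
    period = strata$period[assign_idx],
    protected = protected,
    effort = exp(stats::rnorm(n_sites, mean = log(5), sd = 0.35))
  ) |>
    dplyr::bind_cols(tibble::as_tibble(H))

  # guarantee both classes in every stratum: flip the most eligible site
  for (s in seq_len(n_strata)) {
    idx <- which(assign_idx == s)
    if (all(sites$protected[idx])) {
      sites$protected[idx[which.min(eta[idx])]] <- FALSE
    } else if (!any(sites$protected[idx])) {
      sites$protected[idx[which.max(eta[idx])]] <- TRUE
    }
  }
  sites
}

#' Ground-truth niche specification for one synthetic species
#'
#' Encodes the generative niche of a species in habitat space: the niche
#' centroid on protected land, the displacement applied on unprotected land
#' (a habitat shift), the multiplier on the per-axis niche breadth on
#' unprotected land (a volume expansion), and the expected occurrence count
#' per protection class per period.
#'
#' @param species_id Identifier string.
#' @param center_protected 7-vector on the habitat simplex.
#' @param shift_vector 7-vector displacement (components summing to ~0 keep
#'   the shifted centre on the simplex); default no shift.
#' @param volume_scale Positive breadth multiplier on unprotected land;
#'   default 1 (no expansion).
#' @param niche_sd Strictly positive 7-vector of per-axis niche breadths.
#' @param n_target Expected occurrences per protection class per period.
#' @return A list of class `"niche_spec"`.
#' @export
niche_spec <- function(species_id, center_protected,
                       shift_vector = rep(0, 7), volume_scale = 1,
                       niche_sd = rep(0.08, 7), n_target = 200L) {
  stopifnot(length(center_protected) == 7, length(shift_vector) == 7,
            length(niche_sd) == 7, all(niche_sd > 0), volume_scale > 0,
            all(center_protected >= 0), sum(center_protected) <= 1 + 1e-9)
  structure(list(species_id = species_id,
                 center_protected = as.numeric(center_protected),
                 shift_vector = as.numeric(shift_vector),
                 volume_scale = volume_scale,
                 niche_sd = as.numeric(niche_sd),
                 n_target = as.integer(n_target)),
            class = "niche_spec")
}

#' Simplex-safe displacement of a niche centre along one habitat axis
#'
#' Adds `delta` to the receiving axis and removes mass from every other axis
#' in proportion to the centre's composition, so the displaced centre always
#' stays on the simplex whatever the centre looks like.
#'
#' @param center 7-vector on the habitat simplex.
#' @param delta Displacement added to the receiving axis (must be < 1 -
#'   center[axis]).
#' @param axis Receiving axis index; default the centre's third-largest
#'   component, a habitat common enough that sites near the shifted centre
#'   exist.
#' @return The shift 7-vector (summing to 0).
#' @export
shift_on_simplex <- function(center, delta, axis = NULL) {
  stopifnot(length(center) == 7, delta >= 0)
  if (delta == 0) return(rep(0, 7))
  if (is.null(axis)) axis <- order(center, decreasing = TRUE)[3]
  if (delta >= 1 - center[axis]) stop("displacement too large for this centre", call. = FALSE)
  sv <- rep(0, 7)
  sv[axis] <- delta
  others <- setdiff(seq_len(7), axis)
  sv[others] <- -delta * center[others] / (1 - center[axis])
  sv
}

#' Niche specs for the four change-hypothesis scenarios
#'
#' Builds `n_per_class` species per hypothesis class with strong generative
#' effects: `HP0` no change; `HP1` niche breadth scaled by `hp1_scale`
#' (default 3x) on unprotected land; `HP2` centre displaced by `hp2_delta`
#' (default 0.30, i.e. 3 niche-SDs along the receiving axis) via
#' [shift_on_simplex()]; `HP3` both a displacement (`hp3_delta`, default
#' 0.50) and a 3x breadth scaling, built on a narrower base niche
#' (`hp3_sd`, default 0.055 per axis). The HP3 geometry is deliberately NOT
#' the naive stack of the HP1 and HP2 effects: when the expanded
#' hypervolume is wide enough to engulf the displaced one, the replacement
#' component is zero by construction and the scenario becomes
#' indistinguishable from pure expansion, so a measurable "both" scenario
#' needs a displacement that escapes the expanded niche, and a protected
#' niche narrow enough that the occupied-site spread still reflects the
#' breadth scaling instead of saturating at the habitat availability.
#' Niche centres are drawn from a concentrated version of the site
#' Dirichlet law so species occupy well-populated habitat.
#'
#' @param n_per_class Species per hypothesis class.
#' @param hp2_delta,hp3_delta Centre displacements for HP2 and HP3.
#' @param hp1_scale,hp3_scale Breadth multipliers for HP1 and HP3.
#' @param n_target Expected occurrences per protection class per period.
#' @param niche_sd Common per-axis niche breadth (HP0, HP1, HP2).
#' @param hp3_sd Per-axis breadth of the HP3 protected niche.
#' @param alpha Dirichlet concentrations for drawing niche centres.
#' @param seed Integer seed.
#' @return A list of [niche_spec()] objects with a `true_label` attribute on
#'   each element (`"HP0"` ... `"HP3"`).
#' @export
hp_scenario_specs <- function(n_per_class = 10L, hp2_delta = 0.30,
                              hp3_delta = 0.50, hp1_scale = 3,
                              hp3_scale = 3, n_target = 200L,
                              niche_sd = rep(0.10, 7),
                              hp3_sd = rep(0.055, 7),
                              alpha = default_alpha(), seed = 1L) {
  old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  labels <- rep(c("HP0", "HP1", "HP2", "HP3"), each = n_per_class)
  centers <- rdirichlet_mat(length(labels), alpha * 3)
  specs <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    ctr <- centers[i, ]
    delta <- switch(labels[i], HP2 = hp2_delta, HP3 = hp3_delta, 0)
    vs <- switch(labels[i], HP1 = hp1_scale, HP3 = hp3_scale, 1)
    nsd <- if (labels[i] == "HP3") hp3_sd else niche_sd
    specs[[i]] <- niche_spec(
      species_id = sprintf("sp_%s_%02d", labels[i], (i - 1) %% n_per_class + 1),
      center_protected = ctr,
      shift_vector = shift_on_simplex(ctr, delta),
      volume_scale = vs,
      niche_sd = nsd, n_target = n_target
    )
    attr(specs[[i]], "true_label") <- labels[i]
  }
  specs
}

#' Generate species occurrences over a site table
#'
#' Site occupancy is Bernoulli with probability proportional to a Gaussian
#' kernel of the site's habitat composition around the species' niche centre
#' (the protected-land centre, displaced by the shift vector and with
#' breadth multiplied by the volume scale on unprotected land), rescaled
#' within each protection class x period cell so the expected occurrence
#' count is `n_target`, and capped at 0.95. Species whose expected count in
#' any cell falls below 5 are flagged (they would be filtered downstream).
#'
#' @param sites Site tibble from [generate_sites()].
#' @param specs List of [niche_spec()] objects.
#' @param seed Integer seed.
#' @param prob_cap Upper bound on per-site occupancy probability.
#' @return A tibble `species_id`, `site_id`, `period`; attribute
#'   `"low_expectation"` lists flagged species x cell combinations.
#' @export
generate_occurrences <- function(sites, specs, seed = 1L, prob_cap = 0.95) {
  if (!length(specs)) {
    return(tibble::tibble(species_id = character(), site_id = character(),
                          period = character()))
  }
  stopifnot(all(vapply(specs, inherits, logical(1), "niche_spec")))
  old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  H <- as.matrix(sites[habitat_classes()])
  cell <- paste(sites$protected, sites$period)
  out <- vector("list", length(specs))
  flags <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    kern <- numeric(nrow(sites))
    for (prot in c(TRUE, FALSE)) {
      idx <- sites$protected == prot
      ctr <- sp$center_protected + if (prot) 0 else sp$shift_vector
      sdv <- sp$niche_sd * if (prot) 1 else sp$volume_scale
      D <- sweep(H[idx, , drop = FALSE], 2, ctr)
      D <- sweep(D, 2, sdv, "/")
      kern[idx] <- exp(-0.5 * rowSums(D^2))
    }
    p <- numeric(nrow(sites))
    for (cl in unique(cell)) {
      idx <- cell == cl
      tot <- sum(kern[idx])
      sc <- if (tot > 0) sp$n_target / tot else 0
      p[idx] <- pmin(kern[idx] * sc, prob_cap)
      if (sum(p[idx]) < 5) {
        flags[[length(flags) + 1]] <- tibble::tibble(
          species_id = sp$species_id, cell = cl, expected = sum(p[idx])
        )
      }
    }
    occ <- stats::runif(nrow(sites)) < p
    out[[k]] <- tibble::tibble(
      species_id = sp$species_id,
      site_id = sites$site_id[occ],
      period = sites$period[occ]
    )
  }
  res <- dplyr::bind_rows(out)
  low <- dplyr::bind_rows(flags)
  if (nrow(low)) {
    warning(dplyr::n_distinct(low$species_id),
            " species have expected occurrence count < 5 in some ",
            "protection x period cell", call. = FALSE)
  }
  attr(res, "low_expectation") <- low
  res
}

#' Generate a synthetic trait table
#'
#' Body mass (g) and generation length (years) are drawn jointly lognormal
#' with a configurable correlation (default 0.75, strong enough to trip the
#' collinearity screen). Habitat and diet shares come from Dirichlet laws
#' whose concentration varies across species, giving a spread of Gini
#' specialization scores. When `effect_config` carries non-zero
#' coefficients, the latent trait score `sum(coef * standardized trait)` is
#' returned per species so occurrence generators or tests can couple true
#' shift magnitude to traits with known coefficients.
#'
#' @param specs List of [niche_spec()] objects (or a character vector of
#'   species ids).
#' @param effect_config Named numeric vector of logit-scale coefficients on
#'   any of `log_body_mass`, `habitat_specialization`, `diet_specialization`,
#'   `carnivore`, `red_list_threatened`; default all zero.
#' @param mass_gl_correlation Correlation between log body mass and log
#'   generation length.
#' @param threatened_fraction Marginal probability of threatened status.
#' @param seed Integer seed.
#' @return A tibble with `species_id`, `red_list`, `body_mass`,
#'   `generation_length`, list-columns `habitat_shares` and `diet_shares`,
#'   `vert_diet_prop`, and `trait_effect` (the configured linear predictor).
#' @export
generate_traits <- function(specs, effect_config = NULL,
                            mass_gl_correlation = 0.75,
                            threatened_fraction = 0.25, seed = 1L) {
  ids <- if (is.character(specs)) specs else vapply(specs, `[[`, "", "species_id")
  if (anyDuplicated(ids)) stop("duplicate species ids", call. = FALSE)
  stopifnot(abs(mass_gl_correlation) <= 1)
  old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  n <- length(ids)
  r <- mass_gl_correlation
  z1 <- stats::rnorm(n); z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  log_mass <- log(250) + 1.2 * z1
  log_gl <- log(4) + 0.5 * z2
  hab <- lapply(seq_len(n), function(i) {
    conc <- stats::runif(1, 0.3, 3)
    drop(rdirichlet_mat(1, rep(conc, 7)))
  })
  diet <- lapply(seq_len(n), function(i) {
    conc <- stats::runif(1, 0.3, 3)
    drop(rdirichlet_mat(1, rep(conc, 5)))
  })
  vert <- stats::rbeta(n, 0.8, 2)
  red <- ifelse(stats::runif(n) < threatened_fraction, "threatened", "not_threatened")

  tr <- tibble::tibble(
    species_id = ids,
    red_list = red,
    body_mass = exp(log_mass),
    generation_length = exp(log_gl),
    habitat_shares = hab,
    diet_shares = diet,
    vert_diet_prop = vert
  )
  coefs <- c(log_body_mass = 0, habitat_specialization = 0,
             diet_specialization = 0, carnivore = 0, red_list_threatened = 0)
  if (!is.null(effect_config)) {
    stopifnot(all(names(effect_config) %in% names(coefs)),
              all(is.finite(effect_config)))
    coefs[names(effect_config)] <- effect_config
  }
  std <- function(x) (x - mean(x)) / stats::sd(x)
  eff <- coefs["log_body_mass"] * std(log_mass) +
    coefs["habitat_specialization"] * std(vapply(hab, gini_index, 0)) +
    coefs["diet_specialization"] * std(vapply(diet, gini_index, 0)) +
    coefs["carnivore"] * std(arcsine_sqrt(vert)) +
    coefs["red_list_threatened"] * (red == "threatened")
  tr$trait_effect <- as.numeric(eff)
  tr
}

#' Generate a Yule phylogeny and optional phylogenetically structured effect
#'
#' Simulates a pure-birth tree over the given species, rescaled to unit
#' root-to-tip depth, and (optionally) draws a species-level effect from a
#' multivariate normal whose covariance is the lambda-transformed tree
#' covariance (off-diagonals multiplied by `lambda_true`), so `lambda_true
#' = 0` gives independent effects and `lambda_true = 1` Brownian-motion
#' structure.
#'
#' @param species_ids Character vector of at least 3 unique tip labels.
#' @param lambda_true Signal strength in `[0, 1]` for the generated effect.
#' @param effect_sd Marginal SD of the species effect.
#' @param seed Integer seed.
#' @return A list with `tree` (an `ape` `phylo`), `newick` (the serialized
#'   string) and `effect` (named numeric vector, or NULL when `effect_sd`
#'   is 0).
#' @export
generate_tree <- function(species_ids, lambda_true = 0, effect_sd = 1,
                          seed = 1L) {
  if (length(species_ids) < 3) stop("need at least 3 species", call. = FALSE)
  if (anyDuplicated(species_ids)) stop("duplicate species ids", call. = FALSE)
  stopifnot(lambda_true >= 0, lambda_true <= 1)
  old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  n <- length(species_ids)
  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$tip.label <- species_ids
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth

  effect <- NULL
  if (effect_sd > 0) {
    C <- ape::vcv(tree)
    Cl <- C * lambda_true
    diag(Cl) <- diag(C)
    eff <- drop(rmvnorm_chol(1, Cl * effect_sd^2))
    effect <- stats::setNames(eff, rownames(C))[species_ids]
  }
  list(tree = tree, newick = ape::write.tree(tree), effect = effect)
}

#' Write a synthetic dataset bundle to disk
#'
#' Sites, occurrences and traits as UTF-8 CSV ("." decimal separator), the
#' phylogeny as a Newick file, and the full generator settings as a JSON
#' sidecar for provenance.
#'
#' @param dir Output directory (created if needed).
#' @param sites,occurrences,traits Tibbles from the generators.
#' @param newick Newick string (optional).
#' @param settings Named list echoed to `settings.json`.
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(dir, sites, occurrences, traits = NULL,
                                   newick = NULL, settings = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sites, file.path(dir, "sites.csv"))
  readr::write_csv(occurrences, file.path(dir, "occurrences.csv"))
  if (!is.null(traits)) {
    flat <- traits |>
      dplyr::mutate(
        habitat_shares = purrr::map_chr(.data$habitat_shares,
                                        \(x) paste(x, collapse = ";")),
        diet_shares = purrr::map_chr(.data$diet_shares,
                                     \(x) paste(x, collapse = ";"))
      )
    readr::write_csv(flat, file.path(dir, "traits.csv"))
  }
  if (!is.null(newick)) writeLines(newick, file.path(dir, "tree.nwk"))
  jsonlite::write_json(settings, file.path(dir, "settings.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
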