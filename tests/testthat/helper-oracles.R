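# Shared fixtures and independent oracles used across the test files.

# Small site table with both protection classes in one stratum, fixed habitat.
toy_sites <- function(n = 8, seed = 42) {
  set.seed(seed)
  H <- nichematch:::rdirichlet_mat(n, rep(2, 7))
  colnames(H) <- nichematch:::habitat_classes()
  tibble::tibble(
    site_id = sprintf("T%02d", seq_len(n)),
    zone = "MB", period = "P1",
    protected = rep(c(TRUE, FALSE), length.out = n),
    effort = 5
  ) |> dplyr::bind_cols(tibble::as_tibble(H))
}

# Brute-force maximum-likelihood logistic regression by grid search over
# (intercept, slope); refines the grid around the optimum twice.
grid_logistic <- function(x, y) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  ctr <- c(0, 0); width <- 10
  for (pass in 1:4) {
    b0s <- seq(ctr[1] - width, ctr[1] + width, length.out = 41)
    b1s <- seq(ctr[2] - width, ctr[2] + width, length.out = 41)
    vals <- outer(b0s, b1s, Vectorize(ll))
    ix <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    ctr <- c(b0s[ix[1]], b1s[ix[2]])
    width <- width / 10
  }
  ctr
}

# Reference greedy matcher, written independently of the package version:
# plain loops, no vectorization tricks.
greedy_match_reference <- function(sites, scores, caliper) {
  prot <- which(sites$protected)
  unprot <- which(!sites$protected)
  prot <- prot[order(-scores[prot], sites$site_id[prot])]
  taken <- c()
  pairs <- list()
  for (i in prot) {
    stratum_ok <- sites$zone[unprot] == sites$zone[i] &
      sites$period[unprot] == sites$period[i]
    cand <- setdiff(unprot[stratum_ok], taken)
    if (!length(cand)) next
    d <- abs(scores[cand] - scores[i])
    best <- cand[order(d, sites$site_id[cand])][1]
    if (abs(scores[best] - scores[i]) > caliper) next
    taken <- c(taken, best)
    pairs[[length(pairs) + 1]] <- c(sites$site_id[i], sites$site_id[best])
  }
  do.call(rbind, pairs)
}

# Direct-ML fixed-effects beta regression (mean-precision parameterization),
# the oracle for the mixed-model reduction test.
betareg_oracle <- function(X, y) {
  nll <- function(par) {
    beta <- par[-length(par)]
    phi <- exp(par[length(par)])
    mu <- stats::plogis(drop(X %*% beta))
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  start <- c(rep(0, ncol(X)), log(5))
  fit <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(coef = fit$par[-length(fit$par)], phi = exp(fit$par[length(fit$par)]),
       loglik = -fit$value)
}

# Beta-GLMM data simulator with known coefficients and random-intercept SDs.
simulate_beta_glmm <- function(n_species = 100, n_periods = 4,
                               beta = c(0.5, -0.3, 0, 0, 0),
                               sd_species = 0.3, sd_period = 0.2,
                               phi = 30, seed = 1) {
  set.seed(seed)
  sp <- sprintf("sp%03d", seq_len(n_species))
  pd <- sprintf("P%d", seq_len(n_periods))
  df <- expand.grid(species_id = sp, period = pd, stringsAsFactors = FALSE)
  n <- nrow(df)
  P <- length(beta) - 1
  Xc <- matrix(rnorm(n_species * P), n_species, P,
               dimnames = list(sp, paste0("x", seq_len(P))))
  Xc <- scale(Xc)
  X <- cbind(1, Xc[df$species_id, , drop = FALSE])
  u_sp <- rnorm(n_species, 0, sd_species)
  u_pd <- rnorm(n_periods, 0, sd_period)
  names(u_sp) <- sp; names(u_pd) <- pd
  eta <- drop(X %*% beta) + u_sp[df$species_id] + u_pd[df$period]
  mu <- stats::plogis(eta)
  df$y <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  for (j in seq_len(P)) df[[paste0("x", j)]] <- Xc[df$species_id, j]
  tibble::as_tibble(df)
}
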