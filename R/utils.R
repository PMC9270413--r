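# Seed handling: generator functions are pure given their seed argument and
# leave the caller's RNG state untouched.
local_seed <- function(seed) {
  # force the seed before snapshotting the RNG state: a lazily-evaluated
  # seed argument may itself consume random numbers in the caller
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Derive a bounded per-stage seed from a single pipeline seed, so any stage
# can be replayed in isolation.
derive_seed <- function(seed, stage) {
  offsets <- c(sites = 11L, occurrences = 23L, traits = 37L, tree = 41L,
               match = 53L, niche = 67L, model = 79L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage, call. = FALSE)
  (as.integer(seed) * 97L + offsets[[stage]]) %% 2000000011L
}

# Dirichlet draw via independent gammas; rows sum to one.
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g / rowSums(g)
}

# Multivariate normal draw from a covariance matrix via its Cholesky factor
# (pivoting tolerated for semi-definite inputs).
rmvnorm_chol <- function(n, Sigma) {
  p <- ncol(Sigma)
  L <- tryCatch(chol(Sigma), error = function(e) {
    chol(Sigma + diag(1e-10 * mean(diag(Sigma)), p))
  })
  matrix(stats::rnorm(n * p), n, p) %*% L
}
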