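#' Matching specification
#'
#' Bundles the settings of the site-matching stage: which covariates drive
#' similarity, which columns must match exactly (vegetation zone and land
#' cover period by default), the distance method, and the caliper width for
#' propensity matching (0.25 SD of the propensity scores by default, applied
#' on the probability scale; `caliper_scale = "logit"` switches to the logit
#' scale).
#'
#' @param covariates Character vector of covariate column names (the seven
#'   habitat proportions; add `"effort"` for the bird design, where survey
#'   effort varies strongly between the protected and unprotected databases).
#' @param exact Character vector of exact-match columns.
#' @param method `"propensity"` or `"mahalanobis"`.
#' @param caliper_sd Caliper as a multiple of the propensity-score SD
#'   (propensity method only); 0 disables the caliper.
#' @param caliper_scale `"probability"` or `"logit"`.
#' @param ridge Logical: fall back to a ridge-penalised (1e-4) propensity
#'   fit under perfect separation.
#' @return A list of class `"match_spec"`.
#' @export
match_spec <- function(covariates, exact = c("zone", "period"),
                       method = c("propensity", "mahalanobis"),
                       caliper_sd = 0.25, caliper_scale = c("probability", "logit"),
                       ridge = FALSE) {
  method <- match.arg(method)
  caliper_scale <- match.arg(caliper_scale)
  stopifnot(length(covariates) >= 1, caliper_sd >= 0)
  structure(list(covariates = covariates, exact = exact, method = method,
                 caliper_sd = caliper_sd, caliper_scale = caliper_scale,
                 replacement = FALSE, ridge = ridge),
            class = "match_spec")
}

#' Propensity scores for protection status
#'
#' Logistic regression of the protection indicator on the matching
#' covariates, fitted by iteratively reweighted least squares. Returns the
#' fitted probability of protection for every site, with the coefficient
#' vector attached for audit. Perfect separation raises an error unless
#' `ridge = TRUE`, in which case a weak ridge penalty (1e-4) stabilises the
#' fit.
#'
#' @param sites Site tibble with a logical `protected` column and the
#'   covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param ridge Use a ridge-penalised fit if the unpenalised one separates.
#' @return Numeric vector of scores in (0, 1), one per row of `sites`, with
#'   attribute `"coefficients"`.
#' @export
fit_propensity <- function(sites, covariates, ridge = FALSE) {
  stopifnot("protected" %in% names(sites))
  if (length(unique(sites$protected)) < 2) {
    stop("both protection classes must be present to fit a propensity model",
         call. = FALSE)
  }
  if (anyNA(sites[covariates])) stop("missing covariate values", call. = FALSE)
  df <- as.data.frame(sites[covariates])
  df$.protected <- as.integer(sites$protected)
  form <- stats::reformulate(covariates, response = ".protected")
  fit <- suppressWarnings(
    stats::glm(form, data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  )
  p <- stats::fitted(fit)
  separated <- any(p > 1 - 1e-8) || any(p < 1e-8)
  if (separated) {
    if (!ridge) {
      stop("perfect separation in the propensity model; refit with ridge = TRUE ",
           "to apply a weak (1e-4) ridge penalty", call. = FALSE)
    }
    Xm <- cbind(1, as.matrix(df[covariates]))
    beta <- ridge_logistic(Xm, df$.protected, lambda = 1e-4)
    p <- stats::plogis(drop(Xm %*% beta))
    attr(p, "coefficients") <- stats::setNames(beta, c("(Intercept)", covariates))
    return(p)
  }
  attr(p, "coefficients") <- stats::coef(fit)
  p
}

# Newton iterations for ridge-penalised logistic regression (penalty on all
# coefficients including the intercept is avoided: intercept unpenalised).
ridge_logistic <- function(X, y, lambda, tol = 1e-10, maxit = 100) {
  beta <- numeric(ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    grad <- crossprod(X, y - mu) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    step <- solve(H, grad)
    beta <- beta + drop(step)
    if (sqrt(sum(grad^2)) < tol) break
  }
  beta
}

#' Mahalanobis distance between two covariate vectors
#'
#' Quadratic-form distance `sqrt((x - y)' S^{-1} (x - y))` under a pooled
#' covariance `S`. A near-singular covariance is ridge-regularised
#' (1e-8 on the diagonal) when `regularize = TRUE`, otherwise it errors.
#'
#' @param x,y Numeric covariate vectors of equal length.
#' @param pooled_cov Pooled covariance matrix.
#' @param regularize Add 1e-8 to the diagonal if `pooled_cov` is singular.
#' @return Non-negative scalar distance; symmetric in `x` and `y`.
#' @export
mahalanobis_distance <- function(x, y, pooled_cov, regularize = FALSE) {
  d <- as.numeric(x) - as.numeric(y)
  Sinv <- tryCatch(solve(pooled_cov), error = function(e) NULL)
  if (is.null(Sinv)) {
    if (!regularize) stop("singular pooled covariance; set regularize = TRUE", call. = FALSE)
    Sinv <- solve(pooled_cov + diag(1e-8, ncol(pooled_cov)))
  }
  sqrt(max(drop(t(d) %*% Sinv %*% d), 0))
}

#' Match protected sites to their nearest unprotected counterparts
#'
#' One-to-one greedy nearest-neighbour matching without replacement inside
#' each exact stratum (vegetation zone x period by default). Under the
#' propensity method the distance is the absolute propensity-score
#' difference and candidates farther than `caliper_sd` x SD(scores) are
#' rejected; under the Mahalanobis method the distance is the pooled-
#' covariance quadratic form over the covariates and no caliper applies.
#' Protected sites are processed in descending propensity order (descending
#' mean covariate order for Mahalanobis), ties broken by `site_id`, which
#' makes the pairing fully deterministic.
#'
#' @param sites Site tibble (`site_id`, `protected`, the exact columns and
#'   the covariates).
#' @param spec A [match_spec()].
#' @return A list of class `"matched_pairs"`: `pairs` (tibble of
#'   `protected_site_id`, `unprotected_site_id`, `distance`),
#'   `unmatched_protected` (character vector), `match_rate`, `scores`
#'   (propensity scores, or NULL), `caliper` (absolute caliper width used).
#' @export
match_sites <- function(sites, spec) {
  stopifnot(inherits(spec, "match_spec"),
            all(c("site_id", "protected") %in% names(sites)),
            all(spec$exact %in% names(sites)),
            all(spec$covariates %in% names(sites)))
  if (anyNA(sites[spec$covariates])) stop("missing covariate values", call. = FALSE)

  scores <- NULL; caliper <- Inf
  if (spec$method == "propensity") {
    scores <- fit_propensity(sites, spec$covariates, ridge = spec$ridge)
    sc <- if (spec$caliper_scale == "logit") stats::qlogis(scores) else as.numeric(scores)
    if (spec$caliper_sd > 0) caliper <- spec$caliper_sd * stats::sd(sc)
    key <- sc
  } else {
    S <- pooled_covariance(sites, spec$covariates)
    Sinv <- tryCatch(solve(S), error = function(e) solve(S + diag(1e-8, ncol(S))))
    key <- rowMeans(scale(as.matrix(sites[spec$covariates])))
  }

  stratum <- do.call(paste, c(lapply(spec$exact, function(cl) sites[[cl]]), sep = "\r"))
  prot_idx <- which(sites$protected)
  unprot_idx <- which(!sites$protected)
  ord <- prot_idx[order(-key[prot_idx], sites$site_id[prot_idx])]

  used <- logical(nrow(sites))
  res_p <- character(0); res_u <- character(0); res_d <- numeric(0)
  unmatched <- character(0)
  X <- as.matrix(sites[spec$covariates])
  for (i in ord) {
    cand <- unprot_idx[!used[unprot_idx] & stratum[unprot_idx] == stratum[i]]
    if (!length(cand)) {
      unmatched <- c(unmatched, sites$site_id[i])
      next
    }
    if (spec$method == "propensity") {
      dists <- abs(key[cand] - key[i])
    } else {
      diffs <- sweep(X[cand, , drop = FALSE], 2, X[i, ])
      dists <- sqrt(pmax(rowSums((diffs %*% Sinv) * diffs), 0))
    }
    o <- order(dists, sites$site_id[cand])
    best <- o[1]
    if (dists[best] > caliper) {
      unmatched <- c(unmatched, sites$site_id[i])
      next
    }
    j <- cand[best]
    used[j] <- TRUE
    res_p <- c(res_p, sites$site_id[i])
    res_u <- c(res_u, sites$site_id[j])
    res_d <- c(res_d, dists[best])
  }
  structure(
    list(
      pairs = tibble::tibble(protected_site_id = res_p,
                             unprotected_site_id = res_u,
                             distance = res_d),
      unmatched_protected = unmatched,
      match_rate = length(res_p) / length(prot_idx),
      scores = scores,
      caliper = caliper,
      spec = spec
    ),
    class = "matched_pairs"
  )
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat("Matched pairs:", nrow(x$pairs), "(match rate",
      sprintf("%.1f%%)", 100 * x$match_rate), "\n")
  if (length(x$unmatched_protected)) {
    cat("  unmatched protected sites:", length(x$unmatched_protected), "\n")
  }
  invisible(x)
}

pooled_covariance <- function(sites, covariates) {
  Xp <- as.matrix(sites[sites$protected, covariates, drop = FALSE])
  Xu <- as.matrix(sites[!sites$protected, covariates, drop = FALSE])
  np <- nrow(Xp); nu <- nrow(Xu)
  (stats::cov(Xp) * (np - 1) + stats::cov(Xu) * (nu - 1)) / (np + nu - 2)
}

#' Covariate balance before and after matching
#'
#' Standardized mean difference per covariate — group-mean difference over
#' the pooled SD — computed on all sites ("before") and on the matched pairs
#' only ("after"). The pooled SD of the full pre-matching sample is used as
#' the common denominator so the two columns are on the same scale. A
#' covariate with zero pooled SD is reported as SMD 0 with a warning flag.
#'
#' @param sites Site tibble used for matching.
#' @param pairs A `"matched_pairs"` object from [match_sites()].
#' @param covariates Covariate columns to report; default the matching
#'   covariates stored in the pairs object.
#' @return A tibble with columns `covariate`, `smd_before`, `smd_after`,
#'   `zero_sd` (logical flag).
#' @export
balance_report <- function(sites, pairs, covariates = NULL) {
  stopifnot(inherits(pairs, "matched_pairs"))
  if (!nrow(pairs$pairs)) stop("no matched pairs; balance undefined", call. = FALSE)
  if (is.null(covariates)) covariates <- pairs$spec$covariates
  matched_ids <- c(pairs$pairs$protected_site_id, pairs$pairs$unprotected_site_id)
  after <- sites[sites$site_id %in% matched_ids, , drop = FALSE]
  pooled_sd <- function(cl) {
    sp <- stats::var(sites[[cl]][sites$protected])
    su <- stats::var(sites[[cl]][!sites$protected])
    sqrt((sp + su) / 2)
  }
  mean_diff <- function(d, cl) {
    mean(d[[cl]][d$protected]) - mean(d[[cl]][!d$protected])
  }
  purrr::map_dfr(covariates, function(cl) {
    ps <- pooled_sd(cl)
    zero <- !is.finite(ps) || ps == 0
    if (zero) {
      warning("zero pooled SD for covariate ", cl, "; SMD reported as 0", call. = FALSE)
      return(tibble::tibble(covariate = cl, smd_before = 0, smd_after = 0,
                            zero_sd = TRUE))
    }
    tibble::tibble(covariate = cl,
                   smd_before = mean_diff(sites, cl) / ps,
                   smd_after = mean_diff(after, cl) / ps,
                   zero_sd = FALSE)
  })
}
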