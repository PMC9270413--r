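#' Parse and serialize Newick trees
#'
#' Thin wrappers over `ape` with the validity checks the pipeline needs:
#' unique tip labels and branch lengths present. `parse_newick` round-trips
#' with `ape::write.tree`.
#'
#' @param text A Newick string (or path handled by `ape::read.tree`'s `text`
#'   argument semantics — pass strings here, use `ape::read.tree(file)` for
#'   files).
#' @return An `ape` `phylo` object.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL)
  if (is.null(tree)) stop("malformed Newick string", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  tree
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the shared branch length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip depths.
#' Computed by summing edge lengths along root-to-tip paths.
#'
#' @param tree An `ape` `phylo` with branch lengths.
#' @return A symmetric positive semi-definite species x species matrix with
#'   tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  root <- n + 1L
  nn <- max(tree$edge)
  parent <- integer(nn); elen <- numeric(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_nodes <- vector("list", n)
  depth <- numeric(n)
  for (i in seq_len(n)) {
    node <- i; nodes <- integer(0); d <- 0
    while (node != root) {
      nodes <- c(nodes, node)
      d <- d + elen[node]
      node <- parent[node]
    }
    path_nodes[[i]] <- nodes
    depth[i] <- d
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    C[i, i] <- depth[i]
    if (i < n) for (j in (i + 1):n) {
      shared <- intersect(path_nodes[[i]], path_nodes[[j]])
      C[i, j] <- C[j, i] <- sum(elen[shared])
    }
  }
  C
}

# Profile log-likelihood of a GLS normal model with covariance sigma2 * C_lambda,
# mean profiled analytically. Returns -Inf for non-PD transforms.
lambda_loglik <- function(lambda, y, C) {
  n <- length(y)
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  L <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  logdet <- 2 * sum(log(diag(L)))
  ones <- rep(1, n)
  Ci_y <- backsolve(L, forwardsolve(t(L), y))
  Ci_1 <- backsolve(L, forwardsolve(t(L), ones))
  mu <- sum(Ci_y) / sum(Ci_1)
  r <- y - mu
  q <- sum(r * backsolve(L, forwardsolve(t(L), r)))
  sigma2 <- q / n
  if (sigma2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
}

#' Maximum-likelihood Pagel's lambda for a species-level vector
#'
#' Tests for phylogenetic structure in a per-species quantity (here, mean
#' model residuals) by maximizing the Gaussian likelihood over lambda, the
#' multiplier on the off-diagonals of the phylogenetic covariance matrix:
#' lambda near 0 means phylogenetic independence, lambda near 1 means
#' Brownian-motion structure. The mean and scale are profiled out
#' analytically by generalized least squares; lambda is searched on
#' `[0, lambda_max]` where `lambda_max` is the largest value keeping the
#' transformed covariance positive definite. The likelihood-ratio test
#' against lambda = 0 uses a 1-df chi-square halved at the boundary. On a
#' star phylogeny the likelihood is flat in lambda and the result is
#' flagged uninformative.
#'
#' @param values Named numeric vector (names = species, at least 4) or a
#'   tibble with `species_id` and `value` columns.
#' @param tree An `ape` `phylo` covering all species.
#' @return A list of class `"lambda_result"`: `lambda_hat`, `loglik`,
#'   `loglik0` (at lambda = 0), `lrt_stat`, `p_value`, `lambda_max`,
#'   `uninformative`.
#' @export
pagels_lambda <- function(values, tree) {
  if (is.data.frame(values)) {
    values <- stats::setNames(values$value, values$species_id)
  }
  if (is.null(names(values))) stop("`values` must be named by species", call. = FALSE)
  if (length(values) < 4) stop("need at least 4 species", call. = FALSE)
  missing_sp <- setdiff(names(values), tree$tip.label)
  if (length(missing_sp)) {
    stop("species absent from the tree: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  C <- phylo_vcv(tree)[names(values), names(values)]
  y <- as.numeric(values)

  # largest lambda keeping the transformed matrix positive definite
  pd_at <- function(l) is.finite(lambda_loglik(l, y, C))
  lambda_max <- 1
  if (pd_at(1)) {
    hi <- 1
    while (hi < 4 && pd_at(hi * 1.5)) hi <- hi * 1.5
    lo <- hi
    hi <- hi * 1.5
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (pd_at(mid)) lo <- mid else hi <- mid
    }
    lambda_max <- lo
  } else {
    lo <- 0; hi <- 1
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (pd_at(mid)) lo <- mid else hi <- mid
    }
    lambda_max <- lo
  }

  ll0 <- lambda_loglik(0, y, C)
  grid <- seq(0, lambda_max, length.out = 21)
  gl <- vapply(grid, lambda_loglik, 0, y = y, C = C)
  uninformative <- diff(range(gl[is.finite(gl)])) < 1e-8
  if (uninformative) {
    res <- list(lambda_hat = 0, loglik = ll0, loglik0 = ll0,
                lrt_stat = 0, p_value = 1, lambda_max = lambda_max,
                uninformative = TRUE)
    return(structure(res, class = "lambda_result"))
  }
  # refine around the best grid point
  i_best <- which.max(gl)
  lo <- grid[max(i_best - 1, 1)]; hi <- grid[min(i_best + 1, length(grid))]
  opt <- stats::optimize(lambda_loglik, c(lo, hi), y = y, C = C, maximum = TRUE,
                         tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(0, ll0),
                c(lambda_max, lambda_loglik(lambda_max, y, C)))
  best <- cand[which.max(cand[, 2]), ]
  lrt <- max(2 * (best[2] - ll0), 0)
  p <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  if (lrt == 0) p <- 1
  structure(
    list(lambda_hat = best[1], loglik = best[2], loglik0 = ll0,
         lrt_stat = lrt, p_value = p, lambda_max = lambda_max,
         uninformative = FALSE),
    class = "lambda_result"
  )
}

#' @export
print.lambda_result <- function(x, ...) {
  cat("Pagel's lambda:", format(x$lambda_hat, digits = 4),
      " (logLik", format(x$loglik, digits = 6), ")\n")
  if (x$uninformative) {
    cat("  likelihood flat in lambda (star phylogeny); estimate uninformative\n")
  } else {
    cat("  LRT vs lambda = 0:", format(x$lrt_stat, digits = 4),
        " p =", format(x$p_value, digits = 3), "\n")
  }
  invisible(x)
}

#' @rdname pagels_lambda
#' @param x A `"lambda_result"`.
#' @param ... Unused.
#' @export
glance.lambda_result <- function(x, ...) {
  tibble::tibble(lambda_hat = x$lambda_hat, loglik = x$loglik,
                 loglik0 = x$loglik0, lrt_stat = x$lrt_stat,
                 p_value = x$p_value, lambda_max = x$lambda_max,
                 uninformative = x$uninformative)
}
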