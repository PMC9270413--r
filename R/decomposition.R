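#' Overlap fractions between two hypervolumes
#'
#' Estimates the shared volume `a` and the unique volumes `b` (unique to A)
#' and `c` (unique to B) of two kernel hypervolumes defined on identical
#' axis lists. The intersection volume is estimated by importance sampling
#' both ways — over A's retained samples, the volume of the subset that also
#' falls inside B (density under B at or above B's threshold), and
#' symmetrically — and the two one-sided estimates are averaged to reduce
#' asymmetry bias. Unique volumes follow by subtraction from the total
#' volumes and are clipped at zero.
#'
#' @param hvA,hvB Objects of class `"niche_hypervolume"` with identical
#'   `axes`.
#' @return A tibble with columns `a`, `b`, `c`, `volume_a`, `volume_b`.
#' @export
estimate_overlap_fractions <- function(hvA, hvB) {
  stopifnot(inherits(hvA, "niche_hypervolume"), inherits(hvB, "niche_hypervolume"))
  if (!identical(hvA$axes, hvB$axes)) {
    stop("hypervolumes are defined on different axis lists and cannot be compared",
         call. = FALSE)
  }
  in_b <- density_at(hvB, hvA$samples)$included
  inter_from_a <- sum(1 / hvA$sample_density[in_b]) / hvA$n_samples
  in_a <- density_at(hvA, hvB$samples)$included
  inter_from_b <- sum(1 / hvB$sample_density[in_a]) / hvB$n_samples
  a <- (inter_from_a + inter_from_b) / 2
  tibble::tibble(
    a = a,
    b = max(hvA$volume - a, 0),
    c = max(hvB$volume - a, 0),
    volume_a = hvA$volume,
    volume_b = hvB$volume
  )
}

#' Decompose total niche differentiation into shift and expansion
#'
#' Jaccard-family decomposition of the dissimilarity between two
#' hypervolumes with shared volume `a` and unique volumes `b` and `c`:
#' \deqn{total = (b + c)/(a + b + c)}
#' \deqn{shift = 2\,\min(b, c)/(a + b + c)}
#' \deqn{expansion = |b - c|/(a + b + c)}
#' Total differentiation runs from 0 (complete overlap) to 1 (complete
#' separation) and equals shift + expansion exactly. Shift is the
#' replacement component (the hypervolumes occupy different regions of
#' habitat space); expansion is the unsigned net size difference.
#'
#' @param fractions A one-row data frame or list with elements `a`, `b`, `c`
#'   (all non-negative, not all zero), e.g. from
#'   [estimate_overlap_fractions()].
#' @return A tibble with columns `total`, `shift`, `expansion`.
#' @examples
#' beta_decompose(list(a = 0.2, b = 0.3, c = 0.5))
#' @export
beta_decompose <- function(fractions) {
  a <- fractions$a; b <- fractions$b; cc <- fractions$c
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(cc))
  if (any(a < 0 | b < 0 | cc < 0)) stop("overlap fractions must be non-negative", call. = FALSE)
  denom <- a + b + cc
  if (any(denom <= 0)) stop("a + b + c must be positive", call. = FALSE)
  tibble::tibble(
    total = (b + cc) / denom,
    shift = 2 * pmin(b, cc) / denom,
    expansion = abs(b - cc) / denom
  )
}

#' Compare protected vs unprotected niches for every surviving species pair
#'
#' For each species x period cell retained by [prepare_species_units()],
#' builds the protected and the unprotected hypervolume on the axes that are
#' non-constant in both units (pairs sharing fewer than `min_axes` such axes
#' are skipped), using one common pair bandwidth from
#' [comparison_bandwidth()] so the two volumes are on the same kernel
#' metric, estimates their overlap, and decomposes total niche
#' differentiation into shift and expansion. The signed volume change
#' (unprotected minus protected volume) is carried alongside the unsigned
#' expansion component, to distinguish expansion from contraction.
#'
#' @param units Result of [prepare_species_units()].
#' @param mass_quantile,n_samples Hypervolume settings, see
#'   [build_hypervolume()].
#' @param bandwidth_multiplier Oversmoothing factor for the common pair
#'   bandwidth, see [comparison_bandwidth()].
#' @param seed Integer; per-pair seeds are derived from it deterministically.
#' @param min_axes Minimum number of shared varying axes for a comparison.
#' @return A tibble with one row per compared species x period: `species_id`,
#'   `period`, `total`, `shift`, `expansion`, `signed_volume_change`,
#'   `volume_protected`, `volume_unprotected`, `n_occ_protected`,
#'   `n_occ_unprotected`, `n_axes`.
#' @export
compare_species_niches <- function(units, mass_quantile = 0.95,
                                   n_samples = 20000L,
                                   bandwidth_multiplier = 2.5, seed = 1L,
                                   min_axes = 5L) {
  stopifnot(is.list(units), !is.null(units$units), !is.null(units$pairs))
  pairs <- units$pairs
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sp <- pairs$species_id[i]; pd <- pairs$period[i]
    Mp <- units$units[[sprintf("%s|%s|protected", sp, pd)]]
    Mu <- units$units[[sprintf("%s|%s|unprotected", sp, pd)]]
    shared <- intersect(colnames(Mp), colnames(Mu))
    if (length(shared) < min_axes) next
    Mp <- Mp[, shared, drop = FALSE]
    Mu <- Mu[, shared, drop = FALSE]
    pair_seed <- (derive_seed(seed, "niche") + i * 131L) %% 2000000011L
    bw <- comparison_bandwidth(Mp, Mu, multiplier = bandwidth_multiplier)
    hvP <- build_hypervolume(Mp, bandwidth = bw, mass_quantile = mass_quantile,
                             n_samples = n_samples, seed = pair_seed,
                             min_axes = min_axes)
    hvU <- build_hypervolume(Mu, bandwidth = bw, mass_quantile = mass_quantile,
                             n_samples = n_samples, seed = pair_seed + 1L,
                             min_axes = min_axes)
    fr <- estimate_overlap_fractions(hvP, hvU)
    dec <- beta_decompose(fr)
    out[[i]] <- tibble::tibble(
      species_id = sp, period = pd,
      total = dec$total, shift = dec$shift, expansion = dec$expansion,
      signed_volume_change = hvU$volume - hvP$volume,
      volume_protected = hvP$volume, volume_unprotected = hvU$volume,
      n_occ_protected = hvP$n_occurrences, n_occ_unprotected = hvU$n_occurrences,
      n_axes = length(shared)
    )
  }
  dplyr::bind_rows(out)
}

#' Aggregate per-period comparisons to one row per species
#'
#' Means of total, shift, expansion and signed volume change across the
#' periods in which a species could be compared.
#'
#' @param comparisons Output of [compare_species_niches()].
#' @return One-row-per-species tibble with the averaged components and
#'   `n_periods`.
#' @export
aggregate_comparisons <- function(comparisons) {
  comparisons |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      total = mean(.data$total),
      shift = mean(.data$shift),
      expansion = mean(.data$expansion),
      signed_volume_change = mean(.data$signed_volume_change),
      n_periods = dplyr::n(),
      .groups = "drop"
    )
}
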