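#' Classify a species' niche change against the four change hypotheses
#'
#' Maps a (shift, expansion) pair onto one of four hypothesis labels using a
#' common threshold on each component: `HP0` no change (neither component
#' exceeds the threshold), `HP1` volume expansion only, `HP2` habitat shift
#' only, `HP3` both. Values exactly equal to the threshold count as "no
#' change" (the rule uses strict inequalities).
#'
#' @param shift,expansion Numeric vectors in `[0, 1]` (recycled together).
#' @param threshold Classification threshold in `(0, 1)`; default 0.20.
#' @return Character vector of labels among `"HP0"`, `"HP1"`, `"HP2"`, `"HP3"`.
#' @examples
#' classify_hypothesis(0.6, 0.1) # "HP2"
#' classify_hypothesis(0.5, 0.5) # "HP3"
#' @export
classify_hypothesis <- function(shift, expansion, threshold = 0.20) {
  stopifnot(is.numeric(shift), is.numeric(expansion),
            length(threshold) == 1, threshold > 0, threshold < 1)
  if (any(shift < 0 | shift > 1, na.rm = TRUE) ||
      any(expansion < 0 | expansion > 1, na.rm = TRUE)) {
    stop("`shift` and `expansion` must lie in [0, 1]", call. = FALSE)
  }
  s <- shift > threshold
  e <- expansion > threshold
  dplyr::case_when(
    s & e ~ "HP3",
    s ~ "HP2",
    e ~ "HP1",
    .default = "HP0"
  )
}

#' Label a table of niche comparisons
#'
#' @param comparisons Tibble with `shift` and `expansion` columns (typically
#'   from [compare_species_niches()] or [aggregate_comparisons()]).
#' @inheritParams classify_hypothesis
#' @return The input with a `label` column and a `threshold` column appended.
#' @export
label_comparisons <- function(comparisons, threshold = 0.20) {
  stopifnot(all(c("shift", "expansion") %in% names(comparisons)))
  comparisons |>
    dplyr::mutate(
      label = classify_hypothesis(.data$shift, .data$expansion, threshold),
      threshold = threshold
    )
}

#' Hypothesis counts across a grid of thresholds
#'
#' Recomputes the hypothesis label of every row of `comparisons` at each
#' threshold in `grid` and cross-tabulates, for a robustness display of how
#' the class counts react to the choice of threshold. The `HP0` count is
#' monotone non-decreasing in the threshold.
#'
#' @inheritParams label_comparisons
#' @param grid Numeric vector of thresholds in `(0, 1)`.
#' @return A tibble with columns `threshold`, `label`, `n` (all four labels
#'   present at every threshold, zero-filled).
#' @export
threshold_sensitivity <- function(comparisons, grid = seq(0.1, 0.5, by = 0.05)) {
  if (!length(grid)) stop("`grid` must be non-empty", call. = FALSE)
  stopifnot(all(grid > 0 & grid < 1))
  purrr::map_dfr(grid, function(thr) {
    tibble::tibble(
      threshold = thr,
      label = classify_hypothesis(comparisons$shift, comparisons$expansion, thr)
    )
  }) |>
    dplyr::count(.data$threshold,
                 label = factor(.data$label, levels = c("HP0", "HP1", "HP2", "HP3"))) |>
    tidyr::complete(.data$threshold, .data$label, fill = list(n = 0L)) |>
    dplyr::mutate(label = as.character(.data$label)) |>
    dplyr::arrange(.data$threshold, .data$label)
}
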