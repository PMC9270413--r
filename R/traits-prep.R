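#' Gini specialization index
#'
#' Statistical-dispersion index over a species' habitat or diet shares, used
#' as a specialization score: 0 for a perfect generalist (all shares equal),
#' approaching 1 for an extreme specialist concentrated on one category.
#' The uncorrected sample form is
#' \deqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x),}
#' bounded above by `(n - 1)/n`. `corrected = TRUE` applies the small-sample
#' factor `n/(n - 1)`.
#'
#' @param shares Non-negative numeric vector of shares (at least 2, not all 0).
#' @param corrected Apply the `n/(n-1)` bias correction? Default `FALSE`.
#' @return A single number in `[0, 1)` (or `[0, 1]` when corrected).
#' @examples
#' gini_index(c(0.25, 0.25, 0.25, 0.25)) # 0
#' gini_index(c(1, 0, 0, 0))             # 0.75
#' @export
gini_index <- function(shares, corrected = FALSE) {
  stopifnot(is.numeric(shares))
  if (length(shares) < 2) stop("need at least 2 categories", call. = FALSE)
  if (any(shares < 0)) stop("shares must be non-negative", call. = FALSE)
  if (all(shares == 0)) stop("shares must not be all zero", call. = FALSE)
  n <- length(shares)
  g <- sum(abs(outer(shares, shares, "-"))) / (2 * n^2 * mean(shares))
  if (corrected) g <- g * n / (n - 1)
  g
}

#' Angular (arcsine square root) transform for proportions
#'
#' @param p Numeric vector in `[0, 1]`.
#' @return `asin(sqrt(p))`, in `[0, pi/2]`; strictly increasing.
#' @export
arcsine_sqrt <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("`p` must lie in [0, 1]", call. = FALSE)
  asin(sqrt(p))
}

#' Standardize a vector to zero mean and unit (sample) SD
#'
#' @param x Numeric vector with positive sample standard deviation.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
standardize <- function(x) {
  stopifnot(is.numeric(x))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero or undefined variance; cannot standardize", call. = FALSE)
  (x - mean(x)) / s
}

#' Screen continuous predictors for collinearity
#'
#' Computes pairwise Pearson correlations among the given continuous
#' predictor columns and drops, for every pair with `|r| > r_max`, the member
#' that comes later in `priority` (predictors missing from `priority` rank
#' after all listed ones, in column order). The default priority keeps body
#' mass over generation length, so a built-in mass-generation correlation of
#' about 0.75 removes generation length from the model frame.
#'
#' @param data Data frame containing the predictor columns.
#' @param predictors Character vector of continuous predictor column names.
#' @param r_max Absolute correlation above which one of a pair is dropped.
#' @param priority Character vector; earlier entries are kept preferentially.
#' @return A list with `retained` (character vector), `dropped` (character
#'   vector) and `correlations` (the full Pearson correlation matrix).
#' @export
collinearity_screen <- function(data, predictors,
                                r_max = 0.7,
                                priority = c("log_body_mass", "generation_length")) {
  stopifnot(is.data.frame(data), length(predictors) >= 2)
  missing_cols <- setdiff(predictors, names(data))
  if (length(missing_cols)) {
    stop("predictors not in `data`: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rank_of <- function(v) {
    r <- match(v, priority)
    r[is.na(r)] <- length(priority) + match(v[is.na(r)], predictors)
    r
  }
  cm <- stats::cor(as.data.frame(data)[predictors])
  retained <- predictors
  repeat {
    sub <- cm[retained, retained, drop = FALSE]
    diag(sub) <- 0
    worst <- which(abs(sub) == max(abs(sub)), arr.ind = TRUE)[1, ]
    if (max(abs(sub)) <= r_max) break
    pair <- retained[worst]
    drop_member <- pair[which.max(rank_of(pair))]
    retained <- setdiff(retained, drop_member)
    if (length(retained) < 2) break
  }
  list(retained = retained,
       dropped = setdiff(predictors, retained),
       correlations = cm)
}

#' Assemble the trait model frame for the differentiation models
#'
#' Joins niche-comparison rows (one per species x period) to the trait table
#' and applies the transforms used by the trait models: Gini specialization
#' indices over habitat and diet shares, arcsine-square-root transform of the
#' vertebrate diet proportion ("carnivore"), natural-log body mass and
#' generation length, then standardization of every continuous predictor to
#' zero mean and unit SD, followed by the collinearity screen (default drops
#' generation length when it correlates with body mass at |r| > 0.7).
#'
#' @param comparisons Tibble with `species_id`, `period` and the response
#'   columns `shift` and `expansion` (from [compare_species_niches()]).
#' @param traits Trait tibble with `species_id`, `red_list`, `body_mass`,
#'   `generation_length`, `vert_diet_prop` and list-columns or wide columns
#'   of habitat/diet shares (`habitat_shares`, `diet_shares` as list-columns,
#'   as produced by [generate_traits()]).
#' @param r_max Collinearity threshold passed to [collinearity_screen()].
#' @return A tibble (the model frame) with attributes `retained_predictors`
#'   and `collinearity` recording the screen's outcome.
#' @export
build_model_frame <- function(comparisons, traits, r_max = 0.7) {
  stopifnot(is.data.frame(comparisons), is.data.frame(traits))
  needed <- c("species_id", "red_list", "body_mass", "generation_length",
              "habitat_shares", "diet_shares", "vert_diet_prop")
  missing_cols <- setdiff(needed, names(traits))
  if (length(missing_cols)) {
    stop("trait table lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tr <- traits |>
    dplyr::mutate(
      habitat_specialization = purrr::map_dbl(.data$habitat_shares, gini_index),
      diet_specialization = purrr::map_dbl(.data$diet_shares, gini_index),
      carnivore = arcsine_sqrt(.data$vert_diet_prop),
      log_body_mass = log(.data$body_mass),
      log_generation_length = log(.data$generation_length)
    )

  frame <- comparisons |>
    dplyr::select(dplyr::any_of(c("species_id", "period", "shift", "expansion"))) |>
    dplyr::inner_join(
      dplyr::select(tr, "species_id", "red_list", "habitat_specialization",
                    "diet_specialization", "carnivore", "log_body_mass",
                    "log_generation_length"),
      by = "species_id"
    )

  continuous <- c("habitat_specialization", "diet_specialization", "carnivore",
                  "log_body_mass", "log_generation_length")
  screen <- collinearity_screen(
    frame, continuous, r_max = r_max,
    priority = c("log_body_mass", "log_generation_length")
  )
  frame <- frame |>
    dplyr::select(-dplyr::all_of(screen$dropped)) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(screen$retained), standardize)) |>
    dplyr::mutate(red_list = stats::relevel(factor(.data$red_list), ref = "not_threatened"))
  attr(frame, "retained_predictors") <- screen$retained
  attr(frame, "collinearity") <- screen$correlations
  frame
}
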