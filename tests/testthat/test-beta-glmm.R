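test_that("boundary compression follows its formula and fixes the endpoints", {
  expect_equal(handle_boundaries(0, n = 100), 0.005)
  expect_equal(handle_boundaries(1, n = 100), 0.995)
  expect_equal(handle_boundaries(0.5, n = 17), 0.5)
  y <- seq(0, 1, by = 0.1)
  yc <- handle_boundaries(y, n = 50)
  expect_true(all(yc > 0 & yc < 1))
  expect_true(all(diff(yc) > 0))          # order preserving
  expect_equal((yc * 50 - 0.5) / 49, y)   # invertible
  expect_error(handle_boundaries(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("intercept-only fit of a constant response is zero on the logit scale", {
  df <- tibble::tibble(
    shift = rep(0.5, 40),
    species_id = rep(sprintf("s%d", 1:10), 4),
    period = rep(sprintf("P%d", 1:4), each = 10)
  )
  fit <- suppressWarnings(
    fit_beta_glmm(df, response = "shift", predictors = character(0),
                  groups = NULL)
  )
  expect_equal(fit$fixed_effects$estimate[1], 0, tolerance = 1e-6)
})

test_that("fixed-effects-only fit matches a direct-ML beta regression oracle", {
  set.seed(21)
  n <- 300
  df <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  mu <- plogis(0.4 + 0.6 * df$x1 - 0.5 * df$x2)
  df$shift <- rbeta(n, mu * 25, (1 - mu) * 25)
  df$species_id <- sprintf("s%03d", seq_len(n))
  df$period <- "P1"
  fit <- fit_beta_glmm(df, response = "shift", predictors = c("x1", "x2"),
                       groups = NULL)
  oracle <- betareg_oracle(cbind(1, df$x1, df$x2), df$shift)
  expect_equal(unname(fit$fixed_effects$estimate), oracle$coef, tolerance = 1e-3)
  expect_equal(fit$dispersion, oracle$phi, tolerance = 1e-2)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-4)
})

test_that("random-intercept variance components and coefficients are recovered", {
  df <- simulate_beta_glmm(n_species = 120, n_periods = 4,
                           beta = c(0.5, -0.3, 0.2, 0, 0),
                           sd_species = 0.4, sd_period = 0.2, seed = 22)
  fit <- fit_beta_glmm(df, response = "y",
                       predictors = paste0("x", 1:4),
                       groups = c("species_id", "period"))
  expect_true(fit$converged)
  est <- fit$fixed_effects$estimate
  expect_lt(max(abs(unname(est) - c(0.5, -0.3, 0.2, 0, 0))), 0.15)
  expect_lt(abs(unname(fit$random_sd["species_id"]) - 0.4), 0.15)
  # likelihood ordering against the null model
  null_fit <- fit_beta_glmm(df, response = "y", predictors = character(0),
                            groups = c("species_id", "period"))
  expect_gte(fit$loglik, null_fit$loglik)
  # residual bookkeeping
  expect_length(fit$residuals, nrow(df))
  expect_length(fit$species_residual_means, 120)
  expect_equal(unname(fit$species_residual_means["sp001"]),
               mean(fit$residuals[df$species_id == "sp001"]))
})

test_that("standardizing predictors leaves fitted means unchanged", {
  df <- simulate_beta_glmm(n_species = 60, n_periods = 3,
                           beta = c(0.2, 0.5, 0, 0, 0), seed = 23)
  df$x1_raw <- 3 + 10 * df$x1
  f1 <- fit_beta_glmm(df, response = "y", predictors = "x1",
                      groups = c("species_id", "period"))
  f2 <- fit_beta_glmm(df, response = "y", predictors = "x1_raw",
                      groups = c("species_id", "period"))
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-6)
})

test_that("tidy and glance return the broom-shaped summaries", {
  df <- simulate_beta_glmm(n_species = 40, n_periods = 3, seed = 24)
  fit <- fit_beta_glmm(df, response = "y", predictors = paste0("x", 1:2),
                       groups = c("species_id", "period"))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "conf_low", "conf_high")
                  %in% names(td)))
  expect_equal(td$conf_low, td$estimate - 1.96 * td$std_error)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("logLik", "dispersion", "sd_species_id") %in% names(gl)))
})

test_that("validation diagnostics flag overdispersion but pass a clean fit", {
  df <- simulate_beta_glmm(n_species = 150, n_periods = 3,
                           beta = c(0.3, 0.4, 0, 0, 0), seed = 125)
  fit <- fit_beta_glmm(df, response = "y", predictors = paste0("x", 1:4),
                       groups = c("species_id", "period"))
  v <- model_validation(fit)
  expect_gt(v$dispersion_ratio, 0.8)
  expect_lt(v$dispersion_ratio, 1.2)
  expect_false(v$dispersion_flag)

  # contaminate the response with heavy boundary outliers
  df_bad <- df
  set.seed(126)
  idx <- sample(nrow(df_bad), 60)
  df_bad$y[idx] <- ifelse(runif(60) < 0.5, 0.002, 0.998)
  fit_bad <- fit_beta_glmm(df_bad, response = "y", predictors = paste0("x", 1:4),
                           groups = c("species_id", "period"))
  v_bad <- model_validation(fit_bad)
  expect_gt(v_bad$dispersion_ratio, 1.5)
  expect_true(v_bad$dispersion_flag)

  broken <- fit; broken$converged <- FALSE
  expect_error(model_validation(broken), "converged")
})
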