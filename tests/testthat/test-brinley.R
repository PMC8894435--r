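test_that("an exact affine relation is recovered with zero variance components", {
  means <- toy_means(n_studies = 5L, old_offset = 100, slope = 1)
  fit <- fit_brinley(means, include_interaction = FALSE)
  expect_equal(brinley_coef(fit, "beta2"), 1, tolerance = 1e-6)
  expect_equal(brinley_coef(fit, "beta0"), 100, tolerance = 1e-4)
  expect_equal(brinley_coef(fit, "beta1"), 0, tolerance = 1e-4)
  expect_lt(fit$varcomp$study_intercept_var, 1e-4)
  expect_lt(fit$varcomp$study_slope_var, 1e-6)
  expect_lt(fit$varcomp$residual_var, 1e-4)
  expect_equal(fit$r2_marginal, 1, tolerance = 1e-6)
})

test_that("information-criterion identities hold for both models", {
  fits <- cached_brinley("A")
  for (fit in fits[c("full", "restricted")]) {
    expect_equal(fit$deviance, -2 * fit$loglik)
    expect_equal(fit$aic, fit$deviance + 2 * fit$n_parameters)
    expect_equal(fit$bic, fit$deviance + fit$n_parameters * log(fit$n_obs))
    expect_true(fit$r2_marginal >= 0 && fit$r2_marginal <= 1)
    expect_gte(fit$varcomp$study_intercept_var, 0)
    expect_gte(fit$varcomp$study_slope_var, 0)
    expect_gte(fit$varcomp$residual_var, 0)
    cov_bound <- sqrt(fit$varcomp$study_intercept_var *
                        fit$varcomp$study_slope_var)
    expect_lte(abs(fit$varcomp$intercept_slope_cov), cov_bound + 1e-8)
  }
  expect_equal(fits$restricted$n_parameters, 5L)
  expect_equal(fits$full$n_parameters, 6L)
  expect_gte(fits$full$loglik, fits$restricted$loglik - 1e-3)
})

test_that("pure sampling noise attenuates the slope to the moment oracle", {
  # no between-study signal at all (grand-shift SD 0), only independent
  # sampling noise on each observed mean: the old-on-young slope should
  # collapse toward 0 and agree with the direct moment computation
  # cov(old, young) / var(young) after removing trial-type means
  set.seed(77)
  n <- 100L
  young_c <- 700 + rnorm(n, 0, 50)
  young_i <- 800 + rnorm(n, 0, 50)
  old_c <- 750 + rnorm(n, 0, 50)
  old_i <- 900 + rnorm(n, 0, 50)
  means <- tibble::tibble(
    study_id = rep(sprintf("S%03d", 1:n), each = 2L),
    trial_type = rep(c("congruent", "incongruent"), n),
    young_mean_rt = as.numeric(rbind(young_c, young_i)),
    old_mean_rt = as.numeric(rbind(old_c, old_i))
  )
  yc <- c(young_c - mean(young_c), young_i - mean(young_i))
  oc <- c(old_c - mean(old_c), old_i - mean(old_i))
  mom_slope <- stats::cov(oc, yc) / stats::var(yc)
  expect_lt(abs(mom_slope), 0.2)  # attenuated essentially to zero
  fit <- fit_brinley(means, include_interaction = FALSE)
  expect_lt(abs(brinley_coef(fit, "beta2")), 0.25)
  expect_lt(abs(brinley_coef(fit, "beta2") - mom_slope), 0.1)
})

test_that("marginal R2 has the right limiting behavior", {
  stub <- structure(
    list(fixed_predictor = c(1, 2, 3, 4),
         young = c(700, 800, 700, 800),
         varcomp = list(study_intercept_var = 0, study_slope_var = 0,
                        intercept_slope_cov = 0, residual_var = 0)),
    class = "brinley_fit"
  )
  expect_equal(marginal_r2(stub), 1)
  stub$fixed_predictor <- rep(5, 4)
  stub$varcomp$residual_var <- 2
  expect_equal(marginal_r2(stub), 0)
})

test_that("model comparison applies the chi-square decision rule", {
  mk_stub <- function(include_interaction, deviance, n_par) {
    structure(
      list(include_interaction = include_interaction, deviance = deviance,
           loglik = -deviance / 2, n_obs = 100L, n_parameters = n_par,
           model = NULL),
      class = "brinley_fit"
    )
  }
  cmp0 <- compare_models(mk_stub(TRUE, 500, 6L), mk_stub(FALSE, 500, 5L))
  expect_equal(cmp0$delta_chi2, 0)
  expect_equal(cmp0$p_value, 1)
  expect_equal(cmp0$df_diff, 1L)
  expect_equal(cmp0$preferred_model, "restricted")

  cmp_sig <- compare_models(mk_stub(TRUE, 490, 6L), mk_stub(FALSE, 500, 5L))
  expect_equal(cmp_sig$delta_chi2, 10)
  expect_equal(cmp_sig$p_value, pchisq(10, 1, lower.tail = FALSE))
  expect_equal(cmp_sig$preferred_model, "full")

  expect_error(compare_models(mk_stub(FALSE, 500, 5L), mk_stub(TRUE, 500, 6L)),
               "interaction")
})

test_that("degenerate and undersized means tables are rejected", {
  means <- toy_means(n_studies = 2L)
  expect_error(fit_brinley(means, FALSE), "at least 3 studies")
  m5 <- toy_means(n_studies = 5L)
  expect_error(fit_brinley(m5[-1, ], FALSE), "S01")
  fit <- fit_brinley(m5, FALSE)
  expect_error(brinley_coef(fit, "beta3"), "beta3")
})
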