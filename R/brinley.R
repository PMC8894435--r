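# Study-level Brinley mixed regression: old condition means regressed on
# young condition means with per-study random intercept and slope, fitted by
# full maximum likelihood so the nested (full vs restricted) likelihood-ratio
# comparison is valid.

#' Fit the study-level Brinley mixed model
#'
#' Fits, by full maximum likelihood,
#' \deqn{RT_{old,ij} = \beta_0 + \beta_1 TT_j + \beta_2 RT_{young,ij} +
#'   \beta_3 TT_j RT_{young,ij} + b_{0i} + b_{1i} RT_{young,ij} + \epsilon_{ij}}
#' where \eqn{TT} is trial type coded 0 = congruent, 1 = incongruent, and
#' \eqn{(b_{0i}, b_{1i})} is an unstructured per-study random intercept and
#' slope. The restricted model (`include_interaction = FALSE`) drops the
#' \eqn{\beta_3} term. Reported `n_parameters` follows the convention of
#' counting the fixed effects plus the two random-effect variances (study
#' intercept and study slope), excluding the intercept-slope covariance and
#' the residual, so that `aic = deviance + 2 * n_parameters` and
#' `bic = deviance + n_parameters * log(n_obs)`.
#'
#' Boundary (singular) random-effect fits are allowed and flagged, not
#' errors. On optimizer non-convergence the fit is retried across optimizers
#' and jittered starting values before failing.
#'
#' @param means Study condition means (see [study_condition_means()]).
#' @param include_interaction Include the trial-type-by-slope term
#'   (\eqn{\beta_3})? `TRUE` gives the full model, `FALSE` the restricted.
#' @param estimate_covariance Estimate the random intercept-slope covariance
#'   (default `TRUE`, unstructured); `FALSE` constrains it to zero.
#' @return A `brinley_fit` object: tibble `coefficients` (term, estimate, se,
#'   t, p), list `varcomp`, `loglik`, `deviance`, `aic`, `bic`,
#'   `r2_marginal`, `n_obs`, `n_parameters`, `boundary` flag, and diagnostics.
#' @export
fit_brinley <- function(means, include_interaction,
                        estimate_covariance = TRUE) {
  validate_study_means(means)
  n_study <- length(unique(means$study_id))
  if (n_study < 3L) stop("need at least 3 studies", call. = FALSE)
  per_study <- table(means$study_id)
  if (any(per_study != 2L)) {
    stop("each study needs exactly one row per trial type; offending: ",
         paste(names(per_study)[per_study != 2L], collapse = ", "),
         call. = FALSE)
  }
  dat <- data.frame(
    old = means$old_mean_rt,
    young = means$young_mean_rt,
    tt = as.numeric(means$trial_type == "incongruent"),
    study_id = factor(means$study_id)
  )
  re_term <- if (estimate_covariance) "(1 + young | study_id)" else
    "(1 + young || study_id)"
  rhs <- if (include_interaction) "tt + young + tt:young" else "tt + young"
  form <- stats::as.formula(paste("old ~", rhs, "+", re_term))
  fit <- fit_lmer_restarts(form, dat)
  build_brinley_fit(fit$model, include_interaction, dat, form,
                    notes = fit$notes, optimizer = fit$optimizer)
}

build_brinley_fit <- function(model, include_interaction, dat, formula,
                              notes = character(), optimizer = "bobyqa") {
  coefs <- summary(model)$coefficients
  term_map <- c("(Intercept)" = "beta0", "tt" = "beta1", "young" = "beta2",
                "tt:young" = "beta3")
  coef_tbl <- tibble(
    term = unname(term_map[rownames(coefs)]),
    predictor = rownames(coefs),
    estimate = unname(coefs[, "Estimate"]),
    se = unname(coefs[, "Std. Error"]),
    t = unname(coefs[, "t value"]),
    p = unname(2 * pnorm(-abs(coefs[, "t value"])))
  )

  vc <- lme4::VarCorr(model)$study_id
  varcomp <- list(
    study_intercept_var = vc[1L, 1L],
    study_slope_var = vc[2L, 2L],
    intercept_slope_cov = vc[1L, 2L],
    residual_var = stats::sigma(model)^2
  )

  loglik <- as.numeric(stats::logLik(model))
  n_obs <- nrow(dat)
  n_fixed <- nrow(coefs)
  n_parameters <- n_fixed + 2L
  deviance <- -2 * loglik

  X <- stats::model.matrix(model)
  fixed_predictor <- as.numeric(X %*% lme4::fixef(model))

  out <- structure(
    list(
      include_interaction = include_interaction,
      coefficients = coef_tbl,
      varcomp = varcomp,
      loglik = loglik,
      deviance = deviance,
      n_obs = n_obs,
      n_parameters = n_parameters,
      aic = deviance + 2 * n_parameters,
      bic = deviance + n_parameters * log(n_obs),
      fixed_predictor = fixed_predictor,
      young = dat$young,
      boundary = lme4::isSingular(model, tol = 1e-4),
      convergence_notes = notes,
      optimizer = optimizer,
      formula = formula,
      data = dat,
      model = model
    ),
    class = "brinley_fit"
  )
  out$r2_marginal <- marginal_r2(out)
  out
}

# ML lmer fit with an optimizer cascade and jittered restarts. "Failure to
# converge" warnings trigger a retry; scaling/singularity advisories are kept
# as notes only.
fit_lmer_restarts <- function(formula, data, max_restarts = 5L) {
  attempts <- list(
    list(optimizer = "bobyqa"),
    list(optimizer = "Nelder_Mead"),
    list(optimizer = "nloptwrap")
  )
  best <- NULL
  all_notes <- character()
  try_fit <- function(optimizer, start = NULL) {
    notes <- character()
    model <- withCallingHandlers(
      tryCatch(
        lme4::lmer(formula, data = data, REML = FALSE, start = start,
                   control = lme4::lmerControl(
                     optimizer = optimizer,
                     optCtrl = if (optimizer == "bobyqa") list(maxfun = 2e5) else
                       list(maxit = 2e5),
                     check.conv.singular = "ignore",
                     # two points per study leave exactly as many random
                     # effects as observations; ML still has a well-defined
                     # optimum, so drop lme4's n-obs-vs-n-ranef guard
                     check.nobs.vs.nRE = "ignore",
                     check.nobs.vs.nlev = "ignore"
                   )),
        error = function(e) e
      ),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    list(model = model, notes = notes)
  }
  is_converged <- function(res) {
    !inherits(res$model, "condition") &&
      !any(grepl("failed to converge", res$notes, ignore.case = TRUE))
  }
  for (a in attempts) {
    res <- try_fit(a$optimizer)
    all_notes <- c(all_notes, res$notes)
    if (inherits(res$model, "condition")) {
      all_notes <- c(all_notes, conditionMessage(res$model))
      next
    }
    if (is_converged(res)) {
      return(list(model = res$model, notes = res$notes, optimizer = a$optimizer))
    }
    if (!inherits(res$model, "condition") &&
        (is.null(best) || stats::logLik(res$model) > stats::logLik(best$model))) {
      best <- c(res, optimizer = a$optimizer)
    }
  }
  # jittered restarts from the best point found so far
  if (!is.null(best)) {
    theta0 <- best$model@theta
    lower <- best$model@lower
    for (k in seq_len(max_restarts)) {
      start <- list(theta = pmax(theta0 * (1 + 0.2 * rnorm(length(theta0))),
                                 lower + 1e-6))
      res <- try_fit("bobyqa", start = start)
      all_notes <- c(all_notes, res$notes)
      if (is_converged(res)) {
        return(list(model = res$model, notes = res$notes,
                    optimizer = sprintf("bobyqa (restart %d)", k)))
      }
      if (!inherits(res$model, "condition") &&
          stats::logLik(res$model) > stats::logLik(best$model)) {
        best <- c(res, optimizer = "bobyqa")
      }
    }
    # accept the best non-clean fit but carry the diagnostics
    return(list(model = best$model,
                notes = unique(c(all_notes, "accepted best fit after restarts")),
                optimizer = best$optimizer))
  }
  stop("mixed-model fit failed: ", paste(unique(all_notes), collapse = "; "),
       call. = FALSE)
}

#' Marginal R-squared of a Brinley fit
#'
#' The marginal coefficient of determination for mixed models: the variance
#' of the fixed-effect linear predictor over the observed design divided by
#' that variance plus the random-effect contribution (the per-observation
#' quadratic form \eqn{z_i' \Sigma z_i} with \eqn{z_i = (1, RT_{young,i})},
#' averaged over observations) plus the residual variance.
#'
#' @param fit A `brinley_fit`.
#' @return Fraction in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  var_fixed <- var(fit$fixed_predictor)
  Sigma <- matrix(
    c(fit$varcomp$study_intercept_var, fit$varcomp$intercept_slope_cov,
      fit$varcomp$intercept_slope_cov, fit$varcomp$study_slope_var),
    2L, 2L
  )
  Z <- cbind(1, fit$young)
  var_random <- mean(rowSums((Z %*% Sigma) * Z))
  total <- var_fixed + var_random + fit$varcomp$residual_var
  if (total <= 0) return(0)
  var_fixed / total
}

#' Likelihood-ratio comparison of the full and restricted Brinley models
#'
#' @param full `brinley_fit` with the interaction term.
#' @param restricted `brinley_fit` without it, fitted to the same data.
#' @return A `brinley_comparison`: `delta_chi2`, `df_diff`, `p_value`, and
#'   `preferred_model` (`"full"` iff `p_value < 0.05`).
#' @export
compare_models <- function(full, restricted) {
  stopifnot(inherits(full, "brinley_fit"), inherits(restricted, "brinley_fit"))
  if (!full$include_interaction || restricted$include_interaction) {
    stop("`full` must include the interaction and `restricted` must not",
         call. = FALSE)
  }
  if (full$n_obs != restricted$n_obs) {
    stop("models were fitted to different data", call. = FALSE)
  }
  # Both models share the same random-effects parameterization, so each can
  # be restarted from the other's variance parameters. Iterating until
  # neither improves protects the likelihood-ratio statistic from local
  # optima in either fit (which otherwise inflate or negate it).
  can_refit <- !is.null(full$model) && !is.null(restricted$model)
  for (round in if (can_refit) 1:4 else integer()) {
    improved <- FALSE
    r2 <- refit_from_theta(restricted, full$model@theta)
    if (r2$loglik > restricted$loglik + 1e-6) {
      restricted <- r2
      improved <- TRUE
    }
    f2 <- refit_from_theta(full, restricted$model@theta)
    if (f2$loglik > full$loglik + 1e-6) {
      full <- f2
      improved <- TRUE
    }
    if (!improved) break
  }
  delta <- restricted$deviance - full$deviance
  if (delta < 0 && delta > -1e-3) delta <- 0
  if (delta < 0) {
    stop("full-model log-likelihood below restricted after restarts (delta = ",
         format(delta), "); fits are unreliable", call. = FALSE)
  }
  df_diff <- full$n_parameters - restricted$n_parameters
  p_value <- pchisq(delta, df = df_diff, lower.tail = FALSE)
  structure(
    list(
      delta_chi2 = delta,
      df_diff = df_diff,
      p_value = p_value,
      preferred_model = if (p_value < 0.05) "full" else "restricted",
      full = full,
      restricted = restricted
    ),
    class = "brinley_comparison"
  )
}

# Refit a Brinley model starting from a given variance-parameter (theta)
# vector, via lme4's modular interface. nlminb evaluates the start point
# itself (bobyqa shifts boundary starts into the interior first), so the
# refit's deviance can never exceed the profiled deviance at `theta_start`.
refit_from_theta <- function(fit, theta_start) {
  ctrl <- lme4::lmerControl(
    check.conv.singular = "ignore",
    check.nobs.vs.nRE = "ignore", check.nobs.vs.nlev = "ignore"
  )
  pf <- suppressWarnings(
    lme4::lFormula(fit$formula, data = fit$data, REML = FALSE, control = ctrl)
  )
  devfun <- do.call(lme4::mkLmerDevfun, pf)
  lower <- pf$reTrms$lower
  start <- pmax(theta_start, lower)
  opt_nlm <- stats::nlminb(start = start, objective = devfun, lower = lower)
  cand <- list(par = opt_nlm$par, fval = opt_nlm$objective)
  opt_bob <- tryCatch(
    suppressWarnings(lme4::optimizeLmer(
      devfun, optimizer = "bobyqa", start = start, lower = lower,
      control = list(maxfun = 2e5)
    )),
    error = function(e) NULL
  )
  if (!is.null(opt_bob) && opt_bob$fval < cand$fval) {
    cand <- list(par = opt_bob$par, fval = opt_bob$fval)
  }
  devfun(cand$par)  # leave internal state at the chosen optimum
  opt <- list(par = cand$par, fval = cand$fval, conv = 0L, message = NULL)
  model <- suppressWarnings(
    lme4::mkMerMod(environment(devfun), opt, pf$reTrms, fr = pf$fr)
  )
  build_brinley_fit(model, fit$include_interaction, fit$data, fit$formula,
                    notes = c(fit$convergence_notes, "refit from shared theta"),
                    optimizer = "nlminb/bobyqa (theta restart)")
}

#' Extract one coefficient from a Brinley fit
#'
#' @param fit A `brinley_fit`.
#' @param term One of `"beta0"`, `"beta1"`, `"beta2"`, `"beta3"`.
#' @param what `"estimate"`, `"se"`, `"t"`, or `"p"`.
#' @return Scalar value.
#' @export
brinley_coef <- function(fit, term, what = "estimate") {
  row <- fit$coefficients[fit$coefficients$term == term, ]
  if (nrow(row) != 1L) stop("term not present in fit: ", term, call. = FALSE)
  unname(row[[what]])
}

#' @export
print.brinley_fit <- function(x, ...) {
  cat(sprintf("Brinley mixed model (%s, ML)\n",
              if (x$include_interaction) "full" else "restricted"))
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  cat(sprintf("  random effects: intercept var %.2f, slope var %.4f, cov %.2f, residual var %.2f\n",
              x$varcomp$study_intercept_var, x$varcomp$study_slope_var,
              x$varcomp$intercept_slope_cov, x$varcomp$residual_var))
  cat(sprintf("  n = %d, df = %d, deviance = %.2f, AIC = %.2f, BIC = %.2f, marginal R2 = %.3f\n",
              x$n_obs, x$n_parameters, x$deviance, x$aic, x$bic, x$r2_marginal))
  if (x$boundary) cat("  note: random-effects covariance at boundary (singular fit)\n")
  invisible(x)
}

#' @export
print.brinley_comparison <- function(x, ...) {
  cat(sprintf("Delta chi-square = %.3f on %d df, p = %.4g -> %s model preferred (%s)\n",
              x$delta_chi2, x$df_diff, x$p_value, x$preferred_model,
              if (x$preferred_model == "restricted") "one line sufficient"
              else "two lines necessary"))
  invisible(x)
}
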