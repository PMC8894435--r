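# Three-level multilevel model of trial-level response times: trials within
# participants within studies, random intercepts at both grouping levels.

#' Fit the trial-level three-level multilevel model
#'
#' Fits `rt_ms ~ age * trial_type + (1 | participant_id) + (1 | study_id)`
#' by maximum likelihood, with both factors coded 0/1 (young and congruent as
#' reference). Participant identifiers are globally unique, so the participant
#' intercept is implicitly nested in study. Trial-level residuals are treated
#' as conditionally independent: the analysis model deliberately ignores the
#' generative AR(1) structure. p-values use the normal approximation to t
#' (with around 200,000 trials the degrees-of-freedom correction is
#' numerically irrelevant).
#'
#' @param table A trial table (see [simulate_case()]).
#' @param reml Use REML instead of ML (default `FALSE`; reported numbers use
#'   ML throughout).
#' @return A `trial_mlm_fit`: tibble `fixed_effects` (term, estimate, se, t,
#'   p), list `varcomp` (participant, study and residual variances),
#'   `loglik`, `n_obs`.
#' @export
fit_trial_mlm <- function(table, reml = FALSE) {
  validate_trial_table(table)
  if (length(unique(table$study_id)) < 2L) {
    stop("need at least 2 studies", call. = FALSE)
  }
  dat <- data.frame(
    rt = table$rt_ms,
    age = as.numeric(table$age_group == "old"),
    tt = as.numeric(table$trial_type == "incongruent"),
    participant_id = factor(table$participant_id),
    study_id = factor(table$study_id)
  )
  model <- lme4::lmer(
    rt ~ age * tt + (1 | participant_id) + (1 | study_id),
    data = dat, REML = reml,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore")
  )
  beta <- lme4::fixef(model)
  # on degenerate (noise-free) data the information matrix is singular and
  # summary() fails; estimates are still exact, SEs are reported as NA
  se <- tryCatch(
    suppressWarnings(sqrt(diag(as.matrix(stats::vcov(model))))),
    error = function(e) rep(NA_real_, length(beta))
  )
  tvals <- beta / se
  term_map <- c("(Intercept)" = "intercept", "age" = "age",
                "tt" = "trial_type", "age:tt" = "interaction")
  fixed <- tibble(
    term = unname(term_map[names(beta)]),
    estimate = unname(beta),
    se = unname(se),
    t = unname(tvals),
    p = unname(2 * pnorm(-abs(tvals)))
  )
  vc <- as.data.frame(lme4::VarCorr(model))
  getvar <- function(grp) vc$vcov[vc$grp == grp]
  structure(
    list(
      fixed_effects = fixed,
      varcomp = list(
        participant_intercept_var = getvar("participant_id"),
        study_intercept_var = getvar("study_id"),
        residual_var = getvar("Residual")
      ),
      loglik = as.numeric(stats::logLik(model)),
      n_obs = nrow(dat),
      reml = reml,
      model = model
    ),
    class = "trial_mlm_fit"
  )
}

#' Extract one fixed effect from a trial-level MLM fit
#'
#' @param fit A `trial_mlm_fit`.
#' @param term One of `"intercept"`, `"age"`, `"trial_type"`,
#'   `"interaction"`.
#' @param what `"estimate"`, `"se"`, `"t"`, or `"p"`.
#' @return Scalar value.
#' @export
mlm_coef <- function(fit, term, what = "estimate") {
  row <- fit$fixed_effects[fit$fixed_effects$term == term, ]
  if (nrow(row) != 1L) stop("term not present in fit: ", term, call. = FALSE)
  row[[what]]
}

#' Replicate simulate-and-fit runs for one case
#'
#' Repeats simulate -> trial-level MLM fit at (optionally reduced) design
#' sizes and reports per-replicate fixed-effect estimates and the
#' interaction-test rejection indicator. Used for parameter-recovery and
#' type-I-error checks. Fit failures are recorded per replicate, not fatal.
#'
#' @param case_id Case label `"A"`-`"H"`.
#' @param n_replicates Number of replicates.
#' @param n_studies,n_per_group Reduced design sizes (defaults 10 and 20).
#' @param seed Master seed; per-replicate seeds are derived deterministically.
#' @param library Case library (default [case_library()]).
#' @param alpha Significance level for the rejection indicator (default 0.05).
#' @return Tibble with one row per replicate: `replicate`, `seed`,
#'   `converged`, `est_age`, `est_trial_type`, `est_interaction`,
#'   `p_interaction`, `reject_interaction`.
#' @export
recovery_suite <- function(case_id, n_replicates, n_studies = 10L,
                           n_per_group = 20L, seed = 1L,
                           library = case_library(), alpha = 0.05) {
  spec <- library[[case_id]]
  if (is.null(spec)) stop("unknown case: ", case_id, call. = FALSE)
  spec <- apply_overrides(spec, list(n_studies = n_studies,
                                     n_per_group = n_per_group))
  set.seed(as.integer(seed))
  rep_seeds <- substream_seeds(n_replicates)
  rows <- lapply(seq_len(n_replicates), function(r) {
    res <- tryCatch({
      tab <- simulate_case(spec, seed = rep_seeds[r])
      fit <- fit_trial_mlm(tab)
      tibble(
        replicate = r, seed = rep_seeds[r], converged = TRUE,
        est_age = mlm_coef(fit, "age"),
        est_trial_type = mlm_coef(fit, "trial_type"),
        est_interaction = mlm_coef(fit, "interaction"),
        p_interaction = mlm_coef(fit, "interaction", "p")
      )
    }, error = function(e) {
      tibble(replicate = r, seed = rep_seeds[r], converged = FALSE,
             est_age = NA_real_, est_trial_type = NA_real_,
             est_interaction = NA_real_, p_interaction = NA_real_)
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  out$reject_interaction <- !is.na(out$p_interaction) & out$p_interaction < alpha
  out
}

#' @export
print.trial_mlm_fit <- function(x, ...) {
  cat(sprintf("Trial-level multilevel model (%s), n = %d trials\n",
              if (x$reml) "REML" else "ML", x$n_obs))
  print(as.data.frame(x$fixed_effects), digits = 4, row.names = FALSE)
  cat(sprintf("  variances: participant %.1f, study %.1f, residual %.1f\n",
              x$varcomp$participant_intercept_var, x$varcomp$study_intercept_var,
              x$varcomp$residual_var))
  invisible(x)
}
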