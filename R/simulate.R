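# Trial-level data generator: AR(1)-correlated RT sequences per participant,
# per-study disturbance of the generative cell means, deterministic seeding
# with per-study / per-participant substreams.

#' AR(1) correlation matrix
#'
#' Entry (i, j) equals `rho^|i - j|`: the intertrial correlation structure
#' assumed for consecutive response times.
#'
#' @param n Matrix side (number of trials), `n >= 1`.
#' @param rho Lag-1 autocorrelation in `[0, 1)`.
#' @return An `n x n` symmetric positive-definite matrix with unit diagonal.
#' @export
#' @examples
#' ar1_correlation(3, 0.6)
ar1_correlation <- function(n, rho) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1) {
    stop("`rho` must lie in [0, 1)", call. = FALSE)
  }
  idx <- seq_len(n)
  rho ^ abs(outer(idx, idx, "-"))
}

# Adjusted cell means for one study given its grand shift g and interaction
# increment delta (delta hits the old-incongruent cell only).
adjust_cell_means <- function(spec, g, delta) {
  m <- function(a, t) case_cell(spec, a, t)$mean_rt
  c(
    young_congruent   = m("young", "congruent") + g,
    young_incongruent = m("young", "incongruent") + g,
    old_congruent     = m("old", "congruent") + g,
    old_incongruent   = m("old", "incongruent") + g + delta
  )
}

draw_delta <- function(disturbance, g) {
  switch(disturbance$kind,
    grand_shift = rep(0, length(g)),
    grand_plus_random_interaction =
      rnorm(length(g), 0, disturbance$sigma_interaction),
    grand_plus_systematic_interaction = disturbance$kappa * g
  )
}

# One study's disturbance draw, rejection-sampled so every adjusted cell mean
# stays positive: the disturbance distribution is truncated to the valid
# region (at the defaults the rejection probability is ~1e-4 per study, worst
# for the systematic scheme where delta = kappa * g amplifies negative
# shifts).
draw_study_disturbance_one <- function(spec, max_tries = 1000L) {
  d <- spec$disturbance
  for (try in seq_len(max_tries)) {
    g <- rnorm(1L, 0, d$sigma_study)
    delta <- draw_delta(d, g)
    means <- adjust_cell_means(spec, g, delta)
    if (all(means > 0)) {
      return(list(g = g, delta = delta, means = means))
    }
  }
  stop("could not draw positive cell means after ", max_tries,
       " attempts; disturbance parameters are too large for the cell means",
       call. = FALSE)
}

#' Draw per-study disturbance-adjusted cell means
#'
#' Draws one grand shift `g_i ~ N(0, sigma_study^2)` per study, applied to all
#' four cell means, plus (depending on the scheme) an interaction increment
#' `delta_i` applied to the old-incongruent cell only. Uses the current RNG
#' state; call `set.seed()` first for reproducibility.
#'
#' @param spec A `case_spec`.
#' @param study_count Number of studies to draw.
#' @return Tibble with one row per study: `study_id`, `g`, `delta`, and the
#'   four adjusted cell means `young_congruent`, `young_incongruent`,
#'   `old_congruent`, `old_incongruent` (ms).
#' @export
draw_study_disturbances <- function(spec, study_count = spec$n_studies) {
  validate_case_spec(spec)
  draws <- lapply(seq_len(study_count),
                  function(i) draw_study_disturbance_one(spec))
  out <- tibble(
    study_id = study_label(seq_len(study_count)),
    g = vapply(draws, `[[`, numeric(1L), "g"),
    delta = vapply(draws, `[[`, numeric(1L), "delta")
  )
  means <- t(vapply(draws, `[[`, numeric(4L), "means"))
  dplyr::bind_cols(out, as_tibble(means))
}

study_label <- function(i) sprintf("S%02d", i)

#' Simulate one participant's trial sequence
#'
#' Trial types alternate deterministically (congruent, incongruent,
#' congruent, ...) over the full `2 * n_trials_per_type` sequence. A single
#' standardized AR(1) process `z_t` (mean 0, variance 1, lag-1 correlation
#' `ar_rho`) spans the whole sequence, and the response time at position t is
#' `mean(cell at t) + sd(cell at t) * z_t`. No truncation is applied.
#'
#' @param cell_means Named numeric vector `c(congruent = , incongruent = )`,
#'   the participant's (disturbance-adjusted) cell means in ms.
#' @param cell_sds Named numeric vector of cell SDs in ms, same names.
#' @param n_trials_per_type Trials per trial type.
#' @param ar_rho Lag-1 autocorrelation in `[0, 1)`.
#' @return Tibble with columns `trial_index` (1-based over the full sequence),
#'   `trial_type`, `rt_ms`.
#' @export
simulate_participant <- function(cell_means, cell_sds, n_trials_per_type,
                                 ar_rho) {
  stopifnot(all(TRIAL_TYPES %in% names(cell_means)),
            all(TRIAL_TYPES %in% names(cell_sds)))
  if (ar_rho < 0 || ar_rho >= 1) stop("`ar_rho` must lie in [0, 1)", call. = FALSE)
  n_total <- 2L * as.integer(n_trials_per_type)
  z <- ar1_series(n_total, ar_rho)
  trial_type <- rep(TRIAL_TYPES, n_trials_per_type)
  tibble(
    trial_index = seq_len(n_total),
    trial_type = trial_type,
    rt_ms = as.numeric(cell_means[trial_type] + cell_sds[trial_type] * z)
  )
}

# Stationary standardized AR(1): z1 ~ N(0,1), z_t = rho z_{t-1} + sqrt(1-rho^2) e_t.
ar1_series <- function(n, rho) {
  e <- rnorm(n)
  if (rho == 0 || n == 1L) return(e)
  innov <- c(e[1L], sqrt(1 - rho^2) * e[-1L])
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

#' Simulate a full multi-study case
#'
#' Generates the complete trial table for one case: `n_studies` studies, each
#' with `n_per_group` participants per age group, each with
#' `n_trials_per_type` trials per trial type. Fully reproducible given
#' `(spec, seed)`. Seeding uses per-study and per-participant substreams
#' (each study's substream seed is drawn up front from the master stream, and
#' participant substream seeds likewise within each study), so increasing
#' `n_studies` leaves earlier studies' draws unchanged.
#'
#' @param spec A `case_spec` (see [case_library()]).
#' @param seed Integer master seed.
#' @return A trial table tibble with columns `study_id`, `participant_id`,
#'   `age_group`, `trial_type`, `trial_index`, `rt_ms`.
#' @export
#' @examples
#' lib <- case_library()
#' toy <- apply_overrides(lib$A, list(n_studies = 2, n_per_group = 3))
#' simulate_case(toy, seed = 1)
simulate_case <- function(spec, seed) {
  validate_case_spec(spec)
  set.seed(as.integer(seed))
  study_seeds <- substream_seeds(spec$n_studies)
  studies <- vector("list", spec$n_studies)
  for (i in seq_len(spec$n_studies)) {
    studies[[i]] <- simulate_study(spec, study_id = study_label(i),
                                   study_seed = study_seeds[i])
  }
  dplyr::bind_rows(studies)
}

# Uniform draws keep their prefix when the count grows, so substream seeds for
# studies 1..k are identical whether n_studies is k or larger.
substream_seeds <- function(n) {
  as.integer(floor(runif(n) * 2147483399)) + 1L
}

simulate_study <- function(spec, study_id, study_seed) {
  set.seed(study_seed)
  means4 <- draw_study_disturbance_one(spec)$means
  n_pp <- spec$n_per_group
  pp_seeds <- substream_seeds(2L * n_pp)
  n_total <- 2L * spec$n_trials_per_type
  n_rows <- 2L * n_pp * n_total
  rt <- numeric(n_rows)
  trial_type <- rep(rep(TRIAL_TYPES, spec$n_trials_per_type), 2L * n_pp)
  age <- rep(AGE_GROUPS, each = n_pp * n_total)
  pid <- rep(sprintf("%s_P%03d", study_id, seq_len(2L * n_pp)), each = n_total)
  offset <- 0L
  for (p in seq_len(2L * n_pp)) {
    age_p <- if (p <= n_pp) "young" else "old"
    means <- setNames(means4[paste(age_p, TRIAL_TYPES, sep = "_")], TRIAL_TYPES)
    sds <- setNames(
      vapply(TRIAL_TYPES, function(t) case_cell(spec, age_p, t)$sd_rt, 1),
      TRIAL_TYPES
    )
    set.seed(pp_seeds[p])
    z <- ar1_series(n_total, spec$ar_rho)
    tt <- trial_type[(offset + 1L):(offset + n_total)]
    rt[(offset + 1L):(offset + n_total)] <- means[tt] + sds[tt] * z
    offset <- offset + n_total
  }
  tibble(
    study_id = study_id,
    participant_id = pid,
    age_group = age,
    trial_type = trial_type,
    trial_index = rep(seq_len(n_total), 2L * n_pp),
    rt_ms = rt
  )
}

TRIAL_TABLE_COLS <- c("study_id", "participant_id", "age_group", "trial_type",
                      "trial_index", "rt_ms")

validate_trial_table <- function(table) {
  missing_cols <- setdiff(TRIAL_TABLE_COLS, names(table))
  if (length(missing_cols)) {
    stop("trial table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) == 0L) stop("trial table has no rows", call. = FALSE)
  bad_age <- setdiff(unique(table$age_group), AGE_GROUPS)
  if (length(bad_age)) {
    stop("invalid age_group value(s): ", paste(bad_age, collapse = ", "),
         call. = FALSE)
  }
  bad_tt <- setdiff(unique(table$trial_type), TRIAL_TYPES)
  if (length(bad_tt)) {
    stop("invalid trial_type value(s): ", paste(bad_tt, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(table$rt_ms))) stop("non-finite rt_ms values", call. = FALSE)
  invisible(table)
}

#' Write / read a trial table as CSV
#'
#' Round-trips the long-format trial table with full numeric precision.
#' `read_trial_table()` validates the header and enum columns and fails with a
#' format error naming the offending column.
#'
#' @param table A trial table (see [simulate_case()]).
#' @param path File path.
#' @return `read_trial_table()` returns the validated tibble;
#'   `write_trial_table()` returns `path` invisibly.
#' @export
write_trial_table <- function(table, path) {
  validate_trial_table(table)
  readr::write_csv(table[TRIAL_TABLE_COLS], path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  table <- tryCatch(
    suppressWarnings(readr::read_csv(
      path,
      col_types = readr::cols(
        study_id = readr::col_character(),
        participant_id = readr::col_character(),
        age_group = readr::col_character(),
        trial_type = readr::col_character(),
        trial_index = readr::col_integer(),
        rt_ms = readr::col_double(),
        .default = readr::col_guess()
      ),
      progress = FALSE
    )),
    error = function(e) {
      stop("malformed trial table CSV (", conditionMessage(e), ")", call. = FALSE)
    }
  )
  validate_trial_table(table)
  table[TRIAL_TABLE_COLS]
}
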