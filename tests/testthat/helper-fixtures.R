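# Shared fixtures and a cache for the expensive full-size simulations and
# fits, so multiple test files can reuse one realization per case.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# One full-size realization per case, seed fixed per case.
full_case_seed <- function(case_id) 5000L + match(case_id, LETTERS[1:8])

cached_trials <- function(case_id) {
  cache_get(paste0("trials_", case_id), {
    simulate_case(case_library()[[case_id]], seed = full_case_seed(case_id))
  })
}

cached_means <- function(case_id) {
  cache_get(paste0("means_", case_id), study_condition_means(cached_trials(case_id)))
}

cached_mlm <- function(case_id) {
  cache_get(paste0("mlm_", case_id), fit_trial_mlm(cached_trials(case_id)))
}

cached_brinley <- function(case_id) {
  cache_get(paste0("brinley_", case_id), {
    full <- fit_brinley(cached_means(case_id), include_interaction = TRUE)
    restricted <- fit_brinley(cached_means(case_id), include_interaction = FALSE)
    cmp <- compare_models(full, restricted)
    list(full = cmp$full, restricted = cmp$restricted, comparison = cmp)
  })
}

# A small, fast version of a case for structural tests.
toy_spec <- function(case_id = "A", n_studies = 3L, n_per_group = 4L,
                     n_trials_per_type = 5L, zero_noise = FALSE,
                     sigma_study = NULL) {
  spec <- case_library()[[case_id]]
  overrides <- list(n_studies = n_studies, n_per_group = n_per_group,
                    n_trials_per_type = n_trials_per_type)
  if (zero_noise) {
    cells <- spec$cells
    cells$sd_rt <- 0
    overrides$cells <- cells
    overrides$disturbance <- list(sigma_study = 0)
  } else if (!is.null(sigma_study)) {
    overrides$disturbance <- list(sigma_study = sigma_study)
  }
  apply_overrides(spec, overrides)
}

# Hand-built study means table for geometry and Brinley toys.
toy_means <- function(n_studies = 5L, old_offset = 100, slope = 1) {
  young_c <- seq(650, 750, length.out = n_studies)
  young_i <- young_c + 100
  tibble::tibble(
    study_id = rep(sprintf("S%02d", seq_len(n_studies)), each = 2L),
    trial_type = rep(c("congruent", "incongruent"), n_studies),
    young_mean_rt = as.numeric(rbind(young_c, young_i)),
    old_mean_rt = slope * as.numeric(rbind(young_c, young_i)) + old_offset
  )
}
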