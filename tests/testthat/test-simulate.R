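test_that("ar1_correlation builds the rho^|i-j| matrix", {
  expect_equal(ar1_correlation(3, 0.6),
               matrix(c(1, 0.6, 0.36, 0.6, 1, 0.6, 0.36, 0.6, 1), 3, 3))
  expect_equal(ar1_correlation(2, 0), diag(2))
  expect_equal(ar1_correlation(1, 0.9), matrix(1, 1, 1))
  m <- ar1_correlation(8, 0.6)
  expect_equal(m, t(m))
  expect_true(all(eigen(m, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_error(ar1_correlation(3, 1), "rho")
  expect_error(ar1_correlation(3, -0.1), "rho")
  expect_error(ar1_correlation(0, 0.5), "n")
})

test_that("study disturbances shift cells as each scheme prescribes", {
  lib <- case_library(sigma_study = 0)
  set.seed(11)
  d0 <- draw_study_disturbances(lib$A, 10)
  expect_true(all(d0$young_congruent == 700))
  expect_true(all(d0$old_incongruent == 900))

  # a common shift cancels in the double difference: contrast stays 50 exactly
  lib <- case_library()
  set.seed(12)
  dA <- draw_study_disturbances(lib$A, 50)
  contrast <- (dA$old_incongruent - dA$old_congruent) -
    (dA$young_incongruent - dA$young_congruent)
  expect_equal(contrast, rep(50, 50))
  # and the shift itself moves all four cells identically
  expect_equal(dA$young_congruent - 700, dA$old_congruent - 750)

  # Case G: contrast is 50 + random delta
  set.seed(13)
  dG <- draw_study_disturbances(lib$G, 50)
  contrastG <- (dG$old_incongruent - dG$old_congruent) -
    (dG$young_incongruent - dG$young_congruent)
  expect_equal(contrastG, 50 + dG$delta)
  expect_gt(sd(dG$delta), 0)

  # Case H: delta = kappa * g, so the contrast is a deterministic affine map
  # of the grand shift and correlates perfectly with it
  set.seed(14)
  dH <- draw_study_disturbances(lib$H, 50)
  contrastH <- (dH$old_incongruent - dH$old_congruent) -
    (dH$young_incongruent - dH$young_congruent)
  expect_equal(contrastH, 50 + 1.5 * dH$g)
  expect_equal(cor(dH$g, contrastH), 1, tolerance = 1e-12)
})

test_that("participant sequences alternate trial types and carry the cell means", {
  means <- c(congruent = 700, incongruent = 800)
  sds0 <- c(congruent = 0, incongruent = 0)
  set.seed(21)
  seq0 <- simulate_participant(means, sds0, n_trials_per_type = 5, ar_rho = 0.6)
  expect_equal(seq0$trial_type, rep(c("congruent", "incongruent"), 5))
  expect_equal(seq0$rt_ms, rep(c(700, 800), 5))
  expect_equal(seq0$trial_index, 1:10)
})

test_that("the AR(1) process has the assumed lag structure", {
  means <- c(congruent = 700, incongruent = 800)
  sds <- c(congruent = 150, incongruent = 150)
  n_pp <- 10000L
  lag_cor <- function(z_mat, k) {
    pre <- as.vector(z_mat[, seq_len(ncol(z_mat) - k)])
    post <- as.vector(z_mat[, seq_len(ncol(z_mat) - k) + k])
    cor(pre, post)
  }
  standardize <- function(df) (df$rt_ms - means[df$trial_type]) / sds[df$trial_type]

  set.seed(31)
  z6 <- t(vapply(seq_len(n_pp), function(i) {
    standardize(simulate_participant(means, sds, 5, ar_rho = 0.6))
  }, numeric(10L)))
  for (k in 1:3) {
    expect_lt(abs(lag_cor(z6, k) - 0.6^k), 0.02)
  }
  expect_lt(abs(mean(z6)), 0.02)
  expect_lt(abs(sd(as.vector(z6)) - 1), 0.01)

  set.seed(32)
  z0 <- t(vapply(seq_len(n_pp), function(i) {
    standardize(simulate_participant(means, sds, 5, ar_rho = 0))
  }, numeric(10L)))
  expect_lt(abs(lag_cor(z0, 1)), 0.01)
})

test_that("simulate_case matches the design arithmetic and is deterministic", {
  spec <- toy_spec("A", n_studies = 3L, n_per_group = 4L, n_trials_per_type = 5L)
  tab <- simulate_case(spec, seed = 42)
  expect_equal(nrow(tab), 3 * (4 + 4) * 10)
  counts <- dplyr::count(tab, study_id, participant_id, trial_type)
  expect_true(all(counts$n == 5L))
  by_study <- dplyr::distinct(tab, study_id, participant_id, age_group) |>
    dplyr::count(study_id, age_group)
  expect_true(all(by_study$n == 4L))

  tab2 <- simulate_case(spec, seed = 42)
  expect_identical(tab, tab2)
  tab3 <- simulate_case(spec, seed = 43)
  expect_false(identical(tab, tab3))
})

test_that("adding studies leaves earlier studies' draws unchanged", {
  spec3 <- toy_spec("A", n_studies = 3L)
  spec5 <- toy_spec("A", n_studies = 5L)
  tab3 <- simulate_case(spec3, seed = 7)
  tab5 <- simulate_case(spec5, seed = 7)
  expect_identical(tab3, dplyr::filter(tab5, study_id %in% unique(tab3$study_id)))
})

test_that("simulated cell means track the generative values", {
  tab <- cached_trials("A")
  yc <- tab$rt_ms[tab$age_group == "young" & tab$trial_type == "congruent"]
  # grand shifts (sd 100) dominate the Monte-Carlo error of the grand mean
  se_grand <- sqrt(100^2 / 50 + var(yc) / length(yc))
  expect_lt(abs(mean(yc) - 700), 4 * se_grand)
  oi <- tab$rt_ms[tab$age_group == "old" & tab$trial_type == "incongruent"]
  se_oi <- sqrt(100^2 / 50 + var(oi) / length(oi))
  expect_lt(abs(mean(oi) - 900), 4 * se_oi)
})

test_that("trial tables round-trip through CSV and bad files are rejected", {
  spec <- toy_spec("A", n_studies = 2L, n_per_group = 2L, n_trials_per_type = 3L)
  tab <- simulate_case(spec, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(tab, path)
  back <- read_trial_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))

  # missing rt_ms column
  broken <- tab[setdiff(names(tab), "rt_ms")]
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(broken, path2)
  expect_error(read_trial_table(path2), "rt_ms")

  # empty file is a format error, not an empty table
  path3 <- withr::local_tempfile(fileext = ".csv")
  file.create(path3)
  expect_error(read_trial_table(path3))

  # enum violations are named
  bad <- tab
  bad$trial_type[1] <- "neutral"
  path4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path4)
  expect_error(read_trial_table(path4), "trial_type")
})
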