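test_that("study condition means average trials with equal weight", {
  tab <- tibble::tibble(
    study_id = "S01",
    participant_id = rep(c("S01_P001", "S01_P002"), each = 4L),
    age_group = rep(c("young", "old"), each = 4L),
    trial_type = rep(c("congruent", "congruent", "incongruent", "incongruent"), 2L),
    trial_index = rep(1:4, 2L),
    rt_ms = c(700, 800, 900, 1000, 750, 850, 950, 1050)
  )
  m <- study_condition_means(tab)
  expect_equal(nrow(m), 2L)
  expect_equal(m$young_mean_rt[m$trial_type == "congruent"], 750)
  expect_equal(m$old_mean_rt[m$trial_type == "congruent"], 800)
  expect_equal(m$young_mean_rt[m$trial_type == "incongruent"], 950)
  expect_equal(m$old_mean_rt[m$trial_type == "incongruent"], 1000)
})

test_that("zero-noise generative means pass through aggregation unchanged", {
  spec <- toy_spec("A", zero_noise = TRUE)
  m <- study_condition_means(simulate_case(spec, seed = 3))
  cong <- m[m$trial_type == "congruent", ]
  incong <- m[m$trial_type == "incongruent", ]
  expect_true(all(cong$young_mean_rt == 700))
  expect_true(all(cong$old_mean_rt == 750))
  expect_true(all(incong$young_mean_rt == 800))
  expect_true(all(incong$old_mean_rt == 900))
})

test_that("a full case aggregates to 2 rows per study", {
  m <- cached_means("A")
  expect_equal(nrow(m), 100L)
  expect_true(all(table(m$study_id) == 2L))
  expect_equal(m, dplyr::arrange(m, study_id, trial_type))
})

test_that("pooled-trial means equal means of participant means (balanced design)", {
  tab <- simulate_case(toy_spec("A"), seed = 8)
  m <- study_condition_means(tab)
  by_participant <- tab |>
    dplyr::group_by(study_id, trial_type, age_group, participant_id) |>
    dplyr::summarise(pm = mean(rt_ms), .groups = "drop") |>
    dplyr::group_by(study_id, trial_type, age_group) |>
    dplyr::summarise(mean_rt = mean(pm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = age_group, values_from = mean_rt) |>
    dplyr::arrange(study_id, trial_type)
  expect_equal(m$young_mean_rt, by_participant$young)
  expect_equal(m$old_mean_rt, by_participant$old)
})

test_that("aggregation is invariant to input row order", {
  tab <- simulate_case(toy_spec("A"), seed = 9)
  set.seed(1)
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(study_condition_means(tab), study_condition_means(shuffled))
})

test_that("incomplete studies are a structural error naming the study", {
  tab <- simulate_case(toy_spec("A", n_studies = 2L), seed = 4)
  dropped <- dplyr::filter(
    tab, !(study_id == "S02" & age_group == "old")
  )
  expect_error(study_condition_means(dropped), "S02")
})

test_that("study means round-trip through CSV; extras warn; bad enums error", {
  m <- study_condition_means(simulate_case(toy_spec("A", n_studies = 2L), seed = 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_means(m, path)
  expect_equal(as.data.frame(read_study_means(path)), as.data.frame(m))

  extra <- dplyr::mutate(m, note = "x")
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(extra, path2)
  expect_warning(back <- read_study_means(path2), "extra column")
  expect_equal(names(back), c("study_id", "trial_type", "young_mean_rt", "old_mean_rt"))

  bad <- m
  bad$trial_type[1] <- "baseline"
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path3)
  expect_error(read_study_means(path3), "trial_type")

  path4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(m[setdiff(names(m), "old_mean_rt")], path4)
  expect_error(read_study_means(path4), "old_mean_rt")
})
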