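test_that("segment geometry computes slope and elevation from the condition pairs", {
  # Case A generative means: segment slope (900-750)/(800-700) = 1.5,
  # elevation mean of (750-700, 900-800) = 75
  means_a <- tibble::tibble(
    study_id = "S01",
    trial_type = c("congruent", "incongruent"),
    young_mean_rt = c(700, 800),
    old_mean_rt = c(750, 900)
  )
  geo_a <- segment_geometry(means_a)
  expect_equal(geo_a$slope, 1.5)
  expect_equal(geo_a$elevation, 75)

  # Case C generative means: equal contrasts give slope exactly 1
  means_c <- means_a
  means_c$old_mean_rt <- c(750, 850)
  geo_c <- segment_geometry(means_c)
  expect_equal(geo_c$slope, 1.0)
  expect_equal(geo_c$elevation, 50)

  # Case F generative means: no young spread, slope undefined, elevation 0
  means_f <- tibble::tibble(
    study_id = "S01",
    trial_type = c("congruent", "incongruent"),
    young_mean_rt = c(800, 800),
    old_mean_rt = c(800, 800)
  )
  geo_f <- segment_geometry(means_f)
  expect_true(is.na(geo_f$slope))
  expect_equal(geo_f$elevation, 0)
})

test_that("Case H segment slopes grow with the study's overall response level", {
  m <- cached_means("H")
  geo <- segment_geometry(m)
  expect_equal(nrow(geo), 50L)
  young_cong <- m$young_mean_rt[m$trial_type == "congruent"]
  expect_gt(cor(young_cong, geo$slope), 0.8)
})

test_that("both plot types render non-empty image files", {
  m <- cached_means("A")[1:20, ]
  for (ext in c("svg", "png")) {
    p1 <- withr::local_tempfile(fileext = paste0(".", ext))
    standard_brinley_plot(m, path = p1)
    expect_true(file.exists(p1))
    expect_gt(file.info(p1)$size, 0)
    p2 <- withr::local_tempfile(fileext = paste0(".", ext))
    modified_brinley_plot(m, path = p2)
    expect_true(file.exists(p2))
    expect_gt(file.info(p2)$size, 0)
  }
  expect_error(standard_brinley_plot(m, path = tempfile(fileext = ".pdf")),
               "format")
})

test_that("plot layers carry one point per study-condition and one segment per study", {
  m <- cached_means("A")
  p_std <- standard_brinley_plot(m)
  expect_equal(nrow(p_std$data), 2L * 50L)
  built <- ggplot2::ggplot_build(p_std)
  expect_equal(nrow(built$data[[1]]), 100L)  # scatter layer

  p_mod <- modified_brinley_plot(m)
  built_mod <- ggplot2::ggplot_build(p_mod)
  seg_layer <- built_mod$data[[2]]
  expect_equal(nrow(seg_layer), 50L)
  # shared axis limits so the reference line has visual slope 1
  expect_equal(built_mod$layout$panel_params[[1]]$x.range,
               built_mod$layout$panel_params[[1]]$y.range)
})

test_that("degenerate inputs warn or error as contracted", {
  means_f <- tibble::tibble(
    study_id = rep(c("S01", "S02"), each = 2L),
    trial_type = rep(c("congruent", "incongruent"), 2L),
    young_mean_rt = rep(800, 4L),
    old_mean_rt = c(800, 800, 810, 810)
  )
  expect_warning(standard_brinley_plot(means_f), "zero variance")

  one_study <- means_f[1:2, ]
  expect_error(standard_brinley_plot(one_study), "2 studies")

  missing_cond <- cached_means("A")[-1, ]
  expect_error(modified_brinley_plot(missing_cond), "S01")
  expect_error(segment_geometry(missing_cond), "S01")
})
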