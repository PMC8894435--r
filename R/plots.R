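# Standard and modified Brinley plots. Geometry that the plots display is
# exposed numerically through segment_geometry(); the images themselves are
# only smoke-tested.

plot_limits <- function(values, pad = 0.05) {
  r <- range(values)
  span <- diff(r)
  if (span == 0) span <- max(abs(r), 1)
  c(r[1] - pad * span, r[2] + pad * span)
}

save_plot_file <- function(p, path, width = 6, height = 6) {
  if (is.null(path)) return(invisible(NULL))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("svg", "png")) {
    stop("unsupported image format: ", ext, " (use svg or png)", call. = FALSE)
  }
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}

#' Standard Brinley plot
#'
#' Scatter of old-group mean RT against young-group mean RT, one point per
#' study x trial type, with one ordinary-least-squares fit line per trial
#' type. Faithful to the conventional form: no study-level connections and no
#' identity reference line. Axes share identical limits so a unit slope is
#' visually 45 degrees.
#'
#' @param means Study condition means (see [study_condition_means()]).
#' @param path Optional output file (`.svg` or `.png`); written if non-NULL.
#' @param axis_limits Optional length-2 numeric shared axis limits (ms);
#'   default is the joint data range padded 5%.
#' @param title Plot title.
#' @return The ggplot object, invisibly if `path` is given.
#' @export
standard_brinley_plot <- function(means, path = NULL, axis_limits = NULL,
                                  title = "Standard Brinley plot") {
  validate_study_means(means)
  if (length(unique(means$study_id)) < 2L) {
    stop("need at least 2 studies", call. = FALSE)
  }
  lims <- axis_limits %||%
    plot_limits(c(means$young_mean_rt, means$old_mean_rt))
  degenerate <- means |>
    dplyr::group_by(.data$trial_type) |>
    dplyr::summarise(v = var(.data$young_mean_rt), .groups = "drop")
  fit_lines <- all(degenerate$v > 0)
  if (!fit_lines) {
    warning("young means have zero variance within a trial type; ",
            "fit lines omitted", call. = FALSE)
  }
  p <- ggplot2::ggplot(means, ggplot2::aes(
    x = .data$young_mean_rt, y = .data$old_mean_rt,
    colour = .data$trial_type, shape = .data$trial_type
  )) +
    ggplot2::geom_point(alpha = 0.8)
  if (fit_lines) {
    p <- p + ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                                  linewidth = 0.7)
  }
  p <- p +
    ggplot2::coord_fixed(xlim = lims, ylim = lims) +
    ggplot2::labs(x = "Young mean RT (ms)", y = "Old mean RT (ms)",
                  colour = "Trial type", shape = "Trial type",
                  title = title) +
    ggplot2::theme_classic()
  save_plot_file(p, path)
  if (is.null(path)) p else invisible(p)
}

#' Modified Brinley plot
#'
#' For each study, one line segment connects the congruent condition point
#' `(young_congruent, old_congruent)` to the incongruent point
#' `(young_incongruent, old_incongruent)`; a unit-slope, zero-intercept
#' no-age-difference reference line spans the shared axis range. Studies above
#' the reference line show an age effect; segments steeper than the reference
#' line carry the Age-by-Trial-Type interaction.
#'
#' @inheritParams standard_brinley_plot
#' @return The ggplot object, invisibly if `path` is given.
#' @export
modified_brinley_plot <- function(means, path = NULL, axis_limits = NULL,
                                  title = "Modified Brinley plot") {
  validate_study_means(means)
  segs <- study_segments(means)
  lims <- axis_limits %||%
    plot_limits(c(means$young_mean_rt, means$old_mean_rt))
  points <- means
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$young_congruent, y = .data$old_congruent,
                   xend = .data$young_incongruent, yend = .data$old_incongruent),
      colour = "grey30", alpha = 0.7
    ) +
    ggplot2::geom_point(
      data = points,
      ggplot2::aes(x = .data$young_mean_rt, y = .data$old_mean_rt,
                   colour = .data$trial_type, shape = .data$trial_type),
      size = 1.8
    ) +
    ggplot2::coord_fixed(xlim = lims, ylim = lims) +
    ggplot2::labs(x = "Young mean RT (ms)", y = "Old mean RT (ms)",
                  colour = "Trial type", shape = "Trial type",
                  title = title,
                  caption = "Dashed line: no age difference (identity)") +
    ggplot2::theme_classic()
  save_plot_file(p, path)
  if (is.null(path)) p else invisible(p)
}

# One row per study with both condition points side by side; errors if a
# study lacks a condition.
study_segments <- function(means) {
  wide <- means |>
    tidyr::pivot_wider(
      id_cols = "study_id",
      names_from = "trial_type",
      values_from = c("young_mean_rt", "old_mean_rt")
    )
  needed <- c("young_mean_rt_congruent", "young_mean_rt_incongruent",
              "old_mean_rt_congruent", "old_mean_rt_incongruent")
  if (!all(needed %in% names(wide)) || anyNA(wide[needed])) {
    bad <- if (all(needed %in% names(wide))) {
      wide$study_id[!stats::complete.cases(wide[needed])]
    } else unique(means$study_id)
    stop("study/studies missing a condition: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble(
    study_id = wide$study_id,
    young_congruent = wide$young_mean_rt_congruent,
    young_incongruent = wide$young_mean_rt_incongruent,
    old_congruent = wide$old_mean_rt_congruent,
    old_incongruent = wide$old_mean_rt_incongruent
  )
}

#' Per-study segment geometry of the modified Brinley plot
#'
#' The two numbers the modified plot displays per study: the segment slope
#' `(old_incong - old_cong) / (young_incong - young_cong)` (steeper than 1
#' indicates a study-level Age-by-Trial-Type interaction) and the mean
#' elevation above the identity line, `mean(old - young)` over both
#' conditions (positive indicates an age effect).
#'
#' @param means Study condition means.
#' @return Tibble with columns `study_id`, `slope` (`NA` when the young
#'   means coincide), `elevation` (ms).
#' @export
segment_geometry <- function(means) {
  validate_study_means(means)
  segs <- study_segments(means)
  dx <- segs$young_incongruent - segs$young_congruent
  dy <- segs$old_incongruent - segs$old_congruent
  tibble(
    study_id = segs$study_id,
    slope = ifelse(dx == 0, NA_real_, dy / dx),
    elevation = ((segs$old_congruent - segs$young_congruent) +
                   (segs$old_incongruent - segs$young_incongruent)) / 2
  )
}
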