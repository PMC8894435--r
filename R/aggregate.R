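# Study x trial-type condition means: the analysis unit for Brinley
# regressions and both plot types.

STUDY_MEANS_COLS <- c("study_id", "trial_type", "young_mean_rt", "old_mean_rt")

#' Collapse a trial table to study-level condition means
#'
#' For each study and trial type, averages all young (respectively old)
#' participants' response times, pooling trials and participants with equal
#' trial weight. Under the balanced design this equals the mean of participant
#' means.
#'
#' @param table A trial table (see [simulate_case()]).
#' @return Tibble with one row per study x trial type, columns `study_id`,
#'   `trial_type`, `young_mean_rt`, `old_mean_rt`, ordered by
#'   (`study_id`, `trial_type`).
#' @export
study_condition_means <- function(table) {
  validate_trial_table(table)
  means <- table |>
    dplyr::group_by(.data$study_id, .data$trial_type, .data$age_group) |>
    dplyr::summarise(mean_rt = mean(.data$rt_ms), .groups = "drop")
  incomplete <- means |>
    dplyr::count(.data$study_id) |>
    dplyr::filter(.data$n != 4L)
  if (nrow(incomplete)) {
    stop("study/studies missing an age group or trial type: ",
         paste(incomplete$study_id, collapse = ", "), call. = FALSE)
  }
  means |>
    tidyr::pivot_wider(names_from = "age_group", values_from = "mean_rt") |>
    dplyr::transmute(
      study_id = .data$study_id,
      trial_type = .data$trial_type,
      young_mean_rt = .data$young,
      old_mean_rt = .data$old
    ) |>
    dplyr::arrange(.data$study_id, .data$trial_type)
}

validate_study_means <- function(means) {
  missing_cols <- setdiff(STUDY_MEANS_COLS, names(means))
  if (length(missing_cols)) {
    stop("study means table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(means) == 0L) stop("study means table has no rows", call. = FALSE)
  bad_tt <- setdiff(unique(means$trial_type), TRIAL_TYPES)
  if (length(bad_tt)) {
    stop("invalid trial_type value(s): ", paste(bad_tt, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(means$young_mean_rt)) || !all(is.finite(means$old_mean_rt))) {
    stop("non-finite study means", call. = FALSE)
  }
  invisible(means)
}

#' Write / read a study-condition-means table as CSV
#'
#' The reader also accepts externally produced tables with the same header
#' (e.g. meta-analytic study means), ignoring extra columns with a warning.
#'
#' @param means Tibble as returned by [study_condition_means()].
#' @param path File path.
#' @return `read_study_means()` returns the validated tibble;
#'   `write_study_means()` returns `path` invisibly.
#' @export
write_study_means <- function(means, path) {
  validate_study_means(means)
  readr::write_csv(means[STUDY_MEANS_COLS], path)
  invisible(path)
}

#' @rdname write_study_means
#' @export
read_study_means <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  means <- tryCatch(
    suppressWarnings(readr::read_csv(
      path,
      col_types = readr::cols(
        study_id = readr::col_character(),
        trial_type = readr::col_character(),
        young_mean_rt = readr::col_double(),
        old_mean_rt = readr::col_double(),
        .default = readr::col_guess()
      ),
      progress = FALSE
    )),
    error = function(e) {
      stop("malformed study means CSV (", conditionMessage(e), ")", call. = FALSE)
    }
  )
  validate_study_means(means)
  extra <- setdiff(names(means), STUDY_MEANS_COLS)
  if (length(extra)) {
    warning("ignoring extra column(s) in study means table: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  means[STUDY_MEANS_COLS]
}
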