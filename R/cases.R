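#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @importFrom stats rnorm runif var sd pchisq pnorm setNames
NULL

AGE_GROUPS <- c("young", "old")
TRIAL_TYPES <- c("congruent", "incongruent")
DISTURBANCE_KINDS <- c(
  "grand_shift",
  "grand_plus_random_interaction",
  "grand_plus_systematic_interaction"
)

#' Between-study disturbance scheme
#'
#' Describes how generative cell means are perturbed from study to study.
#' All schemes add a common random shift `g_i ~ N(0, sigma_study^2)` to every
#' cell mean of study *i* (a random shift in the study's grand mean).
#' `grand_plus_random_interaction` additionally adds an independent increment
#' `delta_i ~ N(0, sigma_interaction^2)` to the old-incongruent cell only, so
#' the Age-by-Trial-Type interaction varies randomly across studies.
#' `grand_plus_systematic_interaction` instead adds `delta_i = kappa * g_i` to
#' the old-incongruent cell, so slower studies show systematically larger
#' interactions.
#'
#' @param kind One of `"grand_shift"`, `"grand_plus_random_interaction"`,
#'   `"grand_plus_systematic_interaction"`.
#' @param sigma_study SD (ms) of the per-study grand shift. Default 100.
#' @param sigma_interaction SD (ms) of the random interaction increment; used
#'   only by `grand_plus_random_interaction`. Default 150.
#' @param kappa Dimensionless gain mapping the grand shift to the interaction
#'   increment; used only by `grand_plus_systematic_interaction`. Default 1.5.
#' @return A `disturbance_scheme` list.
#' @export
disturbance_scheme <- function(kind = DISTURBANCE_KINDS,
                               sigma_study = 100,
                               sigma_interaction = 150,
                               kappa = 1.5) {
  kind <- match.arg(kind, DISTURBANCE_KINDS)
  if (!is.numeric(sigma_study) || length(sigma_study) != 1L || sigma_study < 0) {
    stop("`sigma_study` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(sigma_interaction) || length(sigma_interaction) != 1L ||
      sigma_interaction < 0) {
    stop("`sigma_interaction` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa)) {
    stop("`kappa` must be a single finite number", call. = FALSE)
  }
  structure(
    list(kind = kind, sigma_study = sigma_study,
         sigma_interaction = sigma_interaction, kappa = kappa),
    class = "disturbance_scheme"
  )
}

#' Construct a case specification
#'
#' A case specification holds the full parameterization of one simulated
#' multi-study design: the 2 (age group) x 2 (trial type) cell means and SDs,
#' the counts, the intertrial AR(1) correlation, and the between-study
#' disturbance scheme.
#'
#' @param case_id Single-character label (e.g. `"A"`).
#' @param cells Tibble/data.frame with columns `age_group`, `trial_type`,
#'   `mean_rt`, `sd_rt`; exactly one row per age-group x trial-type cell.
#' @param n_per_group Participants per age group per study (default 50).
#' @param n_trials_per_type Trials per trial type per participant (default 20).
#' @param n_studies Number of studies (default 50).
#' @param ar_rho Lag-1 intertrial autocorrelation in `[0, 1)` (default 0.60).
#' @param disturbance A [disturbance_scheme()].
#' @param description Optional one-line description of the case.
#' @return A `case_spec` object.
#' @export
case_spec <- function(case_id, cells,
                      n_per_group = 50L,
                      n_trials_per_type = 20L,
                      n_studies = 50L,
                      ar_rho = 0.60,
                      disturbance = disturbance_scheme("grand_shift"),
                      description = "") {
  cells <- as_tibble(cells)
  spec <- structure(
    list(
      case_id = as.character(case_id),
      cells = cells,
      n_per_group = as.integer(n_per_group),
      n_trials_per_type = as.integer(n_trials_per_type),
      n_studies = as.integer(n_studies),
      ar_rho = as.numeric(ar_rho),
      disturbance = disturbance,
      description = as.character(description)
    ),
    class = "case_spec"
  )
  validate_case_spec(spec)
}

validate_case_spec <- function(spec) {
  stopifnot(inherits(spec, "case_spec"))
  cells <- spec$cells
  needed <- c("age_group", "trial_type", "mean_rt", "sd_rt")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols)) {
    stop("cells table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  combos <- paste(cells$age_group, cells$trial_type)
  expected <- paste(rep(AGE_GROUPS, each = 2L), rep(TRIAL_TYPES, 2L))
  if (nrow(cells) != 4L || !setequal(combos, expected) || anyDuplicated(combos)) {
    stop("cells must contain each (age_group, trial_type) combination exactly once",
         call. = FALSE)
  }
  if (any(cells$mean_rt <= 0) || any(cells$sd_rt < 0)) {
    stop("cell means must be positive and SDs non-negative", call. = FALSE)
  }
  if (spec$n_per_group < 1L || spec$n_trials_per_type < 1L || spec$n_studies < 1L) {
    stop("counts must be at least 1", call. = FALSE)
  }
  if (!is.finite(spec$ar_rho) || spec$ar_rho < 0 || spec$ar_rho >= 1) {
    stop("`ar_rho` must lie in [0, 1)", call. = FALSE)
  }
  if (!inherits(spec$disturbance, "disturbance_scheme")) {
    stop("`disturbance` must be a disturbance_scheme", call. = FALSE)
  }
  spec
}

cells_from_vec <- function(yc, yi, oc, oi, sd_y, sd_o) {
  tibble(
    age_group  = rep(AGE_GROUPS, each = 2L),
    trial_type = rep(TRIAL_TYPES, 2L),
    mean_rt    = c(yc, yi, oc, oi),
    sd_rt      = c(sd_y, sd_y, sd_o, sd_o)
  )
}

#' Look up one cell of a case specification
#'
#' @param spec A `case_spec`.
#' @param age_group `"young"` or `"old"`.
#' @param trial_type `"congruent"` or `"incongruent"`.
#' @return List with `mean_rt` and `sd_rt` (ms).
#' @export
case_cell <- function(spec, age_group, trial_type) {
  age_group <- match.arg(age_group, AGE_GROUPS)
  trial_type <- match.arg(trial_type, TRIAL_TYPES)
  row <- spec$cells[spec$cells$age_group == age_group &
                      spec$cells$trial_type == trial_type, ]
  list(mean_rt = row$mean_rt, sd_rt = row$sd_rt)
}

#' The eight-case simulation library
#'
#' Returns the eight named case specifications of the simulation study.
#' Cases A-F perturb studies by a grand shift only; Case G adds random
#' study-specific interaction variation; Case H ties the interaction increment
#' to the study's grand shift so the interaction grows with overall slowing.
#'
#' @param sigma_study,sigma_interaction,kappa Disturbance parameters applied
#'   to every case; see [disturbance_scheme()] for defaults and meaning.
#' @return Named list of `case_spec` objects, names `"A"` through `"H"`.
#' @export
#' @examples
#' lib <- case_library()
#' case_cell(lib$A, "young", "congruent")
case_library <- function(sigma_study = 100, sigma_interaction = 150,
                         kappa = 1.5) {
  shift <- disturbance_scheme("grand_shift", sigma_study = sigma_study)
  rand_int <- disturbance_scheme("grand_plus_random_interaction",
                                 sigma_study = sigma_study,
                                 sigma_interaction = sigma_interaction)
  sys_int <- disturbance_scheme("grand_plus_systematic_interaction",
                                sigma_study = sigma_study, kappa = kappa)
  list(
    A = case_spec("A", cells_from_vec(700, 800, 750, 900, 150, 200),
                  disturbance = shift,
                  description = "All studies had same interaction"),
    B = case_spec("B", cells_from_vec(700, 800, 750, 1000, 150, 200),
                  disturbance = shift,
                  description = "Increased interaction magnitude"),
    C = case_spec("C", cells_from_vec(700, 800, 750, 850, 150, 200),
                  disturbance = shift,
                  description = "No interaction"),
    D = case_spec("D", cells_from_vec(700, 900, 700, 900, 150, 150),
                  disturbance = shift,
                  description = "Only main effect of trial type"),
    E = case_spec("E", cells_from_vec(700, 700, 900, 900, 150, 150),
                  disturbance = shift,
                  description = "Only main effect of age"),
    F = case_spec("F", cells_from_vec(800, 800, 800, 800, 150, 150),
                  disturbance = shift,
                  description = "All null effects"),
    G = case_spec("G", cells_from_vec(700, 800, 750, 900, 150, 200),
                  disturbance = rand_int,
                  description = "Random study-level interaction sizes"),
    H = case_spec("H", cells_from_vec(700, 800, 750, 900, 150, 200),
                  disturbance = sys_int,
                  description = "Stronger interactions for some studies")
  )
}

#' Generative effect contrasts implied by a case's cell means
#'
#' Age = old - young congruent means; trial type = young incongruent -
#' congruent; interaction = the double difference
#' (old incong - old cong) - (young incong - young cong).
#'
#' @param spec A `case_spec`.
#' @return Named numeric vector (ms) with elements `age`, `trial_type`,
#'   `interaction`.
#' @export
case_contrasts <- function(spec) {
  m <- function(a, t) case_cell(spec, a, t)$mean_rt
  c(
    age = m("old", "congruent") - m("young", "congruent"),
    trial_type = m("young", "incongruent") - m("young", "congruent"),
    interaction = (m("old", "incongruent") - m("old", "congruent")) -
      (m("young", "incongruent") - m("young", "congruent"))
  )
}

#' Read a case-override configuration file
#'
#' YAML (or JSON, a YAML subset) key-value file overriding pieces of a case
#' specification. Recognized keys: `cells` (list of four maps with
#' `age_group`, `trial_type`, `mean_rt`, `sd_rt`), `n_per_group`,
#' `n_trials_per_type`, `n_studies`, `ar_rho`, `disturbance` (map with `kind`,
#' `sigma_study`, `sigma_interaction`, `kappa`), and `seed`.
#'
#' @param path Path to the config file.
#' @return Named list of overrides suitable for [apply_overrides()]; a `seed`
#'   entry, if present, is passed through untouched.
#' @export
read_case_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must contain a key-value mapping", call. = FALSE)
  allowed <- c("cells", "n_per_group", "n_trials_per_type", "n_studies",
               "ar_rho", "disturbance", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg
}

#' Apply overrides to a case specification
#'
#' @param spec A `case_spec`.
#' @param overrides Named list as returned by [read_case_config()] (a `seed`
#'   entry is ignored here).
#' @return The modified, re-validated `case_spec`.
#' @export
apply_overrides <- function(spec, overrides = list()) {
  if (!length(overrides)) return(spec)
  overrides$seed <- NULL
  if (!is.null(overrides$cells)) {
    cells <- overrides$cells
    if (is.data.frame(cells)) {
      spec$cells <- as_tibble(cells)
    } else {
      spec$cells <- dplyr::bind_rows(lapply(cells, as_tibble))
    }
    overrides$cells <- NULL
  }
  if (!is.null(overrides$disturbance)) {
    d <- overrides$disturbance
    cur <- spec$disturbance
    spec$disturbance <- disturbance_scheme(
      kind = d$kind %||% cur$kind,
      sigma_study = d$sigma_study %||% cur$sigma_study,
      sigma_interaction = d$sigma_interaction %||% cur$sigma_interaction,
      kappa = d$kappa %||% cur$kappa
    )
    overrides$disturbance <- NULL
  }
  for (key in names(overrides)) spec[[key]] <- overrides[[key]]
  spec$n_per_group <- as.integer(spec$n_per_group)
  spec$n_trials_per_type <- as.integer(spec$n_trials_per_type)
  spec$n_studies <- as.integer(spec$n_studies)
  validate_case_spec(spec)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.case_spec <- function(x, ...) {
  cat(sprintf("Case %s: %s\n", x$case_id, x$description))
  cat(sprintf("  %d studies x %d participants/group x %d trials/type, AR rho = %.2f\n",
              x$n_studies, x$n_per_group, x$n_trials_per_type, x$ar_rho))
  cat(sprintf("  disturbance: %s (sigma_study = %g", x$disturbance$kind,
              x$disturbance$sigma_study))
  if (x$disturbance$kind == "grand_plus_random_interaction") {
    cat(sprintf(", sigma_interaction = %g", x$disturbance$sigma_interaction))
  }
  if (x$disturbance$kind == "grand_plus_systematic_interaction") {
    cat(sprintf(", kappa = %g", x$disturbance$kappa))
  }
  cat(")\n")
  print(x$cells)
  invisible(x)
}
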