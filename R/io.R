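# CSV dialect: comma-separated, UTF-8, "." decimal, header required.

#' Read and validate a long response table
#'
#' Expected columns: `participant_id`, `item_id`, `category` (PB/PC/AB/AC)
#' and `rating` (1-6) and/or `accept` (0/1).
#'
#' @param path Path to a responses CSV.
#' @return A validated tibble.
#' @export
read_responses <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(d, c("participant_id", "item_id", "category"),
                  basename(path))
  if (!any(c("rating", "accept") %in% names(d))) {
    abort(sprintf("%s must contain a `rating` or `accept` column.", basename(path)))
  }
  bad <- which(!d$category %in% DILEMMA_CATEGORIES)
  if (length(bad) > 0) {
    abort(sprintf("%s row %d: unknown category `%s`.",
                  basename(path), bad[1], d$category[bad[1]]))
  }
  if ("rating" %in% names(d)) {
    bad <- which(!d$rating %in% 1:6)
    if (length(bad) > 0) {
      abort(sprintf("%s row %d: rating `%s` outside 1..6.",
                    basename(path), bad[1], d$rating[bad[1]]))
    }
  }
  if ("accept" %in% names(d)) {
    bad <- which(!d$accept %in% 0:1)
    if (length(bad) > 0) {
      abort(sprintf("%s row %d: accept `%s` not 0/1.",
                    basename(path), bad[1], d$accept[bad[1]]))
    }
  }
  d$participant_id <- as.character(d$participant_id)
  d
}

#' Read and validate a participant covariates table
#'
#' Expected columns: `participant_id`, `gender`, `age`, `pss10_1` ..
#' `pss10_10` (optionally `pss14_*`), `mc_1` .. `mc_13`, `acute_stress`,
#' `attention_pass`.
#'
#' @param path Path to a covariates CSV.
#' @return A validated tibble.
#' @export
read_covariates <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(d, c("participant_id", "gender", "age",
                       paste0("pss10_", 1:10), paste0("mc_", 1:13),
                       "acute_stress", "attention_pass"),
                  basename(path))
  d$participant_id <- as.character(d$participant_id)
  d
}

#' Read and validate a battery definition table
#'
#' @param path Path to a battery CSV with columns `item_id`, `story_id`,
#'   `category`, `presentation_order`.
#' @return A validated tibble.
#' @export
read_battery <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_battery(d)
  d
}

#' Write a simulated cohort to a directory in the documented CSV dialect
#'
#' Writes `responses.csv`, `covariates.csv` (observable columns only),
#' `truth.csv` (latent stress and true tree parameters) and `battery.csv`.
#'
#' @param cohort A list as returned by [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    responses = file.path(dir, "responses.csv"),
    covariates = file.path(dir, "covariates.csv"),
    truth = file.path(dir, "truth.csv"),
    battery = file.path(dir, "battery.csv")
  )
  readr::write_csv(cohort$responses, paths["responses"], progress = FALSE)
  readr::write_csv(participant_records(cohort$participants),
                   paths["covariates"], progress = FALSE)
  readr::write_csv(truth_table(cohort$participants), paths["truth"],
                   progress = FALSE)
  readr::write_csv(cohort$battery, paths["battery"], progress = FALSE)
  invisible(paths)
}

#' Write a study report to a directory
#'
#' Tables go to CSV (`correlations.csv`, `parameter_summaries.csv`,
#' `estimates.csv`, `exclusions.csv`); settings, seed and tallies go to
#' `report.json`.
#'
#' @param report A `study_report` from [run_replication_pipeline()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    correlations = file.path(dir, "correlations.csv"),
    summaries = file.path(dir, "parameter_summaries.csv"),
    estimates = file.path(dir, "estimates.csv"),
    exclusions = file.path(dir, "exclusions.csv"),
    report = file.path(dir, "report.json")
  )
  readr::write_csv(report$correlations, paths["correlations"], progress = FALSE)
  readr::write_csv(report$parameter_summaries, paths["summaries"], progress = FALSE)
  readr::write_csv(report$estimates, paths["estimates"], progress = FALSE)
  excl <- dplyr::bind_rows(report$exclusions$screening, report$exclusions$cni)
  readr::write_csv(excl, paths["exclusions"], progress = FALSE)
  jsonlite::write_json(
    list(
      n_input = report$exclusions$n_input,
      n_retained = report$exclusions$n_retained,
      n_cni_analyzed = report$exclusions$n_cni_analyzed,
      settings = unclass(report$settings),
      seed = report$seed
    ),
    paths["report"], auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(paths)
}
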