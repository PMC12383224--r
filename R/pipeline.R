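#' Settings for the replication pipeline
#'
#' @param mode Analysis mode: `"binary"` (default) recodes ratings and runs
#'   all four frameworks; `"continuous"` runs the CAN decomposition on raw
#'   mean ratings only (the other frameworks are defined on accept/reject
#'   data); `"both"` runs both arms.
#' @param covariates Covariate columns partialled out of every
#'   stress-parameter correlation (default gender, age, social-desirability
#'   total). `gender` is entered as a 0/1 indicator; the coding direction
#'   does not affect `|r|`.
#' @param alpha Significance level for the power columns.
#' @param tails Tail convention for correlation power (default `"one"`).
#' @param mc_key Social-desirability key (13 binary values).
#' @param pss_version PSS version used as the stress score (10 or 14).
#' @param n_items Battery size required for completeness screening.
#' @param cni_n_starts Restarts for each participant-level CNI fit.
#' @param seed Seed echoed into the report (the pipeline itself is
#'   deterministic given its inputs).
#' @return A list of class `pipeline_settings`.
#' @export
pipeline_settings <- function(mode = c("binary", "continuous", "both"),
                              covariates = c("gender", "age", "mc_total"),
                              alpha = 0.05,
                              tails = c("one", "two"),
                              mc_key = rep_len(c(1L, 0L), 13),
                              pss_version = 10,
                              n_items = 24,
                              cni_n_starts = 20,
                              seed = NULL) {
  structure(
    list(mode = match.arg(mode), covariates = covariates, alpha = alpha,
         tails = match.arg(tails), mc_key = mc_key,
         pss_version = as.integer(pss_version), n_items = as.integer(n_items),
         cni_n_starts = cni_n_starts, seed = seed),
    class = "pipeline_settings"
  )
}

#' Total PSS score for every row of a covariate table
#'
#' @param covariates Tibble with `pss10_1` .. `pss10_10` (or `pss14_*`)
#'   columns.
#' @param version 10 or 14.
#' @param reverse_items Reverse-keyed positions (defaults to the standard
#'   keying).
#' @return Integer vector of totals.
#' @export
score_pss_table <- function(covariates, version = 10, reverse_items = NULL) {
  version <- as.integer(match.arg(as.character(version), c("10", "14")))
  cols <- sprintf("pss%d_%d", version, seq_len(version))
  require_columns(covariates, cols, "covariates")
  m <- as.matrix(covariates[, cols])
  assert_numeric_in(as.vector(m), 0, 4, "PSS items", integer = TRUE)
  reverse_items <- reverse_items %||% pss_reverse_items(version)
  if (length(reverse_items) > 0) m[, reverse_items] <- 4 - m[, reverse_items]
  as.integer(rowSums(m))
}

# Pearson r and two-sided p against zero correlation (no adjustment); the
# fast path used inside replicate loops.
#' @noRd
cor_pvalue <- function(x, y) {
  r <- cor(x, y)
  df <- length(x) - 2
  tval <- r * sqrt(df) / sqrt(1 - r^2)
  c(r = r, p = 2 * pt(-abs(tval), df))
}

#' @noRd
prepare_covariate_columns <- function(data, covariates, mc_key, pss_version) {
  if ("mc_total" %in% covariates && !"mc_total" %in% names(data)) {
    cols <- paste0("mc_", 1:13)
    require_columns(data, cols, "covariates")
    m <- as.matrix(data[, cols])
    data$mc_total <- as.integer(colSums(t(m) == mc_key))
  }
  if ("gender" %in% covariates && is.character(data$gender)) {
    data$gender <- as.integer(factor(data$gender)) - 1L
  }
  data
}

#' Run the full measurement-and-association pipeline on one dataset
#'
#' Executes, in order: covariate scoring (PSS total, social-desirability
#' total), participant screening, rating recoding and per-category
#' aggregation, the four estimator frameworks, and covariate-adjusted partial
#' correlations of the stress score with every decision parameter (with
#' Cohen's d equivalents and achieved power). CNI correlations are computed
#' on the non-excluded, successfully fitted subset only.
#'
#' @param responses Long response tibble (`participant_id`, `item_id`,
#'   `category` and `rating` or `accept`).
#' @param covariates Participant covariate tibble (see
#'   [draw_participants()] / the covariates CSV dialect).
#' @param settings A [pipeline_settings()] object.
#' @param battery Optional battery definition; when supplied, `category` is
#'   joined from it and its size drives the completeness screen.
#' @return An object of class `study_report`: a list with elements
#'   `correlations`, `parameter_summaries`, `estimates` (one row per
#'   participant with all parameters), `exclusions`, `settings`, `seed`.
#' @export
run_replication_pipeline <- function(responses, covariates,
                                     settings = pipeline_settings(),
                                     battery = NULL) {
  stopifnot(inherits(settings, "pipeline_settings"))
  require_columns(covariates, "participant_id", "covariates")
  n_items <- if (!is.null(battery)) nrow(battery) else settings$n_items

  covariates <- prepare_covariate_columns(covariates, settings$covariates,
                                          settings$mc_key, settings$pss_version)
  covariates$pss_total <- score_pss_table(covariates, settings$pss_version)

  screen <- screen_participants(covariates, responses, n_items = n_items)
  kept <- screen$participant_id[screen$retained]
  responses <- dplyr::filter(responses, .data$participant_id %in% kept)
  covariates <- dplyr::filter(covariates, .data$participant_id %in% kept)
  if (length(kept) == 0) abort("no participants survive screening.")

  run_binary <- settings$mode %in% c("binary", "both")
  run_continuous <- settings$mode %in% c("continuous", "both")
  if (run_continuous && !"rating" %in% names(responses)) {
    abort("continuous mode requires raw 1-6 ratings in the responses.")
  }

  estimates <- tibble::tibble(participant_id = kept)
  if (run_binary) {
    prof_b <- aggregate_profiles(responses, battery, mode = "binary")
    prof_cells <- dplyr::rename_with(
      dplyr::select(prof_b, "participant_id", dplyr::all_of(DILEMMA_CATEGORIES)),
      ~ paste0("p_", .x), dplyr::all_of(DILEMMA_CATEGORIES))
    estimates <- estimates |>
      dplyr::left_join(prof_cells, by = "participant_id") |>
      dplyr::left_join(
        dplyr::rename(fit_traditional(prof_b), trad_p_action = "p_action"),
        by = "participant_id") |>
      dplyr::left_join(dplyr::select(fit_pd(prof_b), -"d_defined"),
                       by = "participant_id") |>
      dplyr::left_join(
        dplyr::select(fit_cni(prof_b, n_starts = settings$cni_n_starts),
                      "participant_id", "C_cni", "N_cni", "I_cni",
                      "gsq", "fit_p", "excluded", "error"),
        by = "participant_id") |>
      dplyr::left_join(fit_can(prof_b), by = "participant_id")
  }
  if (run_continuous) {
    prof_c <- aggregate_profiles(responses, battery, mode = "continuous")
    cont <- fit_can(prof_c)
    names(cont)[names(cont) != "participant_id"] <-
      paste0(names(cont)[names(cont) != "participant_id"], "_cont")
    estimates <- dplyr::left_join(estimates, cont, by = "participant_id")
  }

  analysed <- dplyr::left_join(
    estimates,
    dplyr::select(covariates, "participant_id", "pss_total",
                  dplyr::any_of(settings$covariates)),
    by = "participant_id")

  param_cols <- intersect(
    c("trad_p_action", "U", "D", "C_cni", "N_cni", "I_cni",
      "C_can", "A_can", "N_can",
      "C_can_cont", "A_can_cont", "N_can_cont"),
    names(analysed))

  correlations <- purrr::map_dfr(param_cols, function(par) {
    rows <- analysed
    if (par %in% c("C_cni", "N_cni", "I_cni")) {
      rows <- dplyr::filter(rows, !is.na(.data$excluded), !.data$excluded,
                            is.na(.data$error))
    }
    rows <- rows[!is.na(rows[[par]]), , drop = FALSE]
    if (nrow(rows) <= length(settings$covariates) + 2 || sd(rows[[par]]) == 0) {
      return(tibble::tibble(x = "pss_total", y = par, r = NA_real_,
                            n = nrow(rows), k = length(settings$covariates),
                            df = NA_integer_, p = NA_real_,
                            d_equiv = NA_real_, power = NA_real_))
    }
    partial_correlation(rows, "pss_total", par,
                        covariates = settings$covariates,
                        alpha = settings$alpha, tails = settings$tails)
  })
  correlations <- dplyr::rename(correlations, parameter = "y")

  parameter_summaries <- purrr::map_dfr(param_cols, function(par) {
    v <- analysed[[par]]
    v <- v[!is.na(v)]
    tibble::tibble(parameter = par, mean = mean(v), sd = sd(v), n = length(v))
  })

  screening_tally <- dplyr::count(dplyr::filter(screen, !.data$retained),
                                  .data$reason, name = "n")
  cni_tally <- if (run_binary) {
    tibble::tibble(
      reason = c("cni_poor_fit", "cni_error"),
      n = c(sum(estimates$excluded, na.rm = TRUE),
            sum(!is.na(estimates$error)))
    )
  } else {
    tibble::tibble(reason = character(), n = integer())
  }
  exclusions <- list(
    n_input = nrow(screen),
    n_retained = length(kept),
    screening = screening_tally,
    cni = cni_tally,
    n_cni_analyzed = if (run_binary) {
      sum(!is.na(estimates$excluded) & !estimates$excluded &
            is.na(estimates$error))
    } else NA_integer_
  )

  structure(
    list(correlations = correlations,
         parameter_summaries = parameter_summaries,
         estimates = estimates,
         exclusions = exclusions,
         settings = settings,
         seed = settings$seed),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Moral-dilemma study report (%d retained of %d participants)\n",
              x$exclusions$n_retained, x$exclusions$n_input))
  cat("\nStress-parameter partial correlations:\n")
  print(as.data.frame(x$correlations), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @rdname run_replication_pipeline
#' @param x A `study_report`.
#' @param ... Unused.
#' @export
tidy.study_report <- function(x, ...) x$correlations

#' @rdname run_replication_pipeline
#' @export
glance.study_report <- function(x, ...) {
  tibble::tibble(
    n_input = x$exclusions$n_input,
    n_retained = x$exclusions$n_retained,
    n_cni_analyzed = x$exclusions$n_cni_analyzed,
    n_parameters = nrow(x$parameter_summaries),
    alpha = x$settings$alpha,
    mode = x$settings$mode
  )
}

#' @rdname run_replication_pipeline
#' @param object A `study_report`.
#' @export
autoplot.study_report <- function(object, ...) {
  d <- dplyr::filter(object$correlations, !is.na(.data$r))
  # Fisher-z 95% CI for display
  d$lo <- tanh(atanh(d$r) - 1.96 / sqrt(d$n - d$k - 3))
  d$hi <- tanh(atanh(d$r) + 1.96 / sqrt(d$n - d$k - 3))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$parameter, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "partial correlation with stress (95% CI)") +
    ggplot2::theme_minimal()
}
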