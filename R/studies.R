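#' Dichotomization Type-I-error / power study
#'
#' For each replicate, simulates a Likert-rating cohort from `config`,
#' analyses the *same* cohort twice — CAN parameters computed on recoded
#' accept/reject data (the dichotomized arm) and on raw mean ratings (the
#' continuous arm) — and tests the Pearson correlation between the PSS-10
#' total and each CAN parameter at level `alpha`. With `coupling = 0` in the
#' config, the null is true and the rejection rates estimate each arm's
#' Type I error; with nonzero coupling they estimate power. Using identical
#' cohorts across arms isolates the effect of the scoring choice.
#'
#' @param config A [sim_config()]; its `coupling` defines the regime.
#' @param replicates Number of simulated cohorts (default `config$replicates`).
#' @param alpha Test level (default 0.05).
#' @param seed Master seed; each replicate uses a child seed.
#' @return A tibble of class `dichotomization_study` with columns
#'   `parameter`, `method`, `rejections`, `replicates`, `rejection_rate`,
#'   `mc_se` (binomial Monte-Carlo standard error). The full p-value table is
#'   attached as the `"p_values"` attribute.
#' @export
run_dichotomization_study <- function(config, replicates = NULL, alpha = 0.05,
                                      seed = NULL) {
  config <- validate_sim_config(config)
  replicates <- replicates %||% config$replicates
  seed <- seed %||% config$seed
  params <- c("C_can", "A_can", "N_can")
  methods <- c("dichotomized", "continuous")

  pvals <- array(NA_real_, dim = c(replicates, 3, 2),
                 dimnames = list(NULL, params, methods))
  for (r in seq_len(replicates)) {
    cohort <- simulate_cohort(config, response_mode = "likert",
                              seed = child_seed(seed, sprintf("rep%06d", r)))
    pss <- score_pss_table(cohort$participants, 10)
    prof_b <- aggregate_profiles(cohort$responses, mode = "binary")
    prof_c <- aggregate_profiles(cohort$responses, mode = "continuous")
    can_b <- fit_can(prof_b)
    can_c <- fit_can(prof_c)
    stopifnot(identical(can_b$participant_id, cohort$participants$participant_id))
    for (p in params) {
      pvals[r, p, "dichotomized"] <- cor_pvalue(pss, can_b[[p]])["p"]
      pvals[r, p, "continuous"] <- cor_pvalue(pss, can_c[[p]])["p"]
    }
  }

  out <- tidyr::expand_grid(parameter = params, method = methods)
  out <- dplyr::mutate(
    out,
    rejections = purrr::map2_int(.data$parameter, .data$method,
                                 ~ sum(pvals[, .x, .y] < alpha)),
    replicates = replicates,
    rejection_rate = .data$rejections / replicates,
    mc_se = sqrt(.data$rejection_rate * (1 - .data$rejection_rate) / replicates)
  )
  p_long <- tidyr::pivot_longer(
    dplyr::bind_cols(
      tibble::tibble(replicate = seq_len(replicates)),
      tibble::as_tibble(matrix(pvals, nrow = replicates,
                               dimnames = list(NULL, as.vector(outer(params, methods,
                                                                     paste, sep = ".")))))
    ),
    -"replicate", names_to = c("parameter", "method"), names_sep = "\\.",
    values_to = "p"
  )
  attr(out, "p_values") <- p_long
  attr(out, "alpha") <- alpha
  class(out) <- c("dichotomization_study", class(out))
  out
}

#' @rdname run_dichotomization_study
#' @param object A `dichotomization_study`.
#' @param ... Unused.
#' @export
autoplot.dichotomization_study <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$parameter, y = .data$rejection_rate,
                               fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$rejection_rate - 2 * .data$mc_se,
                   ymax = .data$rejection_rate + 2 * .data$mc_se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "rejection rate", fill = "scoring") +
    ggplot2::theme_minimal()
}

#' Parameter-recovery study for the CNI and CAN estimators
#'
#' Simulates binary per-category counts from fixed true tree parameters,
#' re-estimates them with [cni_fit()] and [can_params()], and reports bias
#' and RMSE per parameter as a function of the number of items per category.
#' CAN estimates are compared against their tree-implied targets
#' (`C`, `(1-C) N`, and the implied grand mean), since CAN measures those
#' contrasts by construction.
#'
#' @param true Named vector `c(C=, N=, I=)` of generating tree parameters.
#' @param items_per_category Integer vector of battery sizes to compare
#'   (default `c(6, 24, 96)`).
#' @param replicates Simulated participants per battery size (default 500).
#' @param seed Master seed.
#' @param n_starts Restarts per CNI fit.
#' @return A tibble of class `recovery_study`: `items_per_category`,
#'   `framework`, `parameter`, `truth`, `mean_estimate`, `bias`, `rmse`,
#'   `n_fitted`, `replicates`.
#' @export
run_recovery_study <- function(true = c(C = 0.2, N = 0.25, I = 0.4),
                               items_per_category = c(6, 24, 96),
                               replicates = 500, seed = NULL, n_starts = 20) {
  stopifnot(all(c("C", "N", "I") %in% names(true)))
  p_cells <- unlist(cni_predict(true[["C"]], true[["N"]], true[["I"]]),
                    use.names = FALSE)
  can_truth <- c(
    C_can = true[["C"]],
    A_can = mean(p_cells),
    N_can = (1 - true[["C"]]) * true[["N"]]
  )

  purrr::map_dfr(items_per_category, function(ipc) {
    k <- with_seed_or_ambient(
      child_seed(seed, sprintf("draws_ipc%d", ipc)),
      matrix(rbinom(replicates * 4, ipc, rep(p_cells, each = replicates)),
             ncol = 4, dimnames = list(NULL, DILEMMA_CATEGORIES)))
    cni_est <- matrix(NA_real_, replicates, 3,
                      dimnames = list(NULL, c("C", "N", "I")))
    for (r in seq_len(replicates)) {
      fit <- tryCatch(cni_fit(k[r, ], ipc, n_starts = n_starts),
                      error = function(e) NULL)
      if (!is.null(fit)) cni_est[r, ] <- c(fit$C, fit$N, fit$I)
    }
    v <- k / ipc
    can_est <- can_params(v[, "PB"], v[, "PC"], v[, "AB"], v[, "AC"],
                          scale = "binary")

    summarise_par <- function(est, truth, framework, parameter) {
      ok <- !is.na(est)
      tibble::tibble(
        items_per_category = ipc, framework = framework, parameter = parameter,
        truth = truth,
        mean_estimate = mean(est[ok]),
        bias = mean(est[ok]) - truth,
        rmse = sqrt(mean((est[ok] - truth)^2)),
        n_fitted = sum(ok), replicates = replicates
      )
    }
    dplyr::bind_rows(
      summarise_par(cni_est[, "C"], true[["C"]], "cni", "C"),
      summarise_par(cni_est[, "N"], true[["N"]], "cni", "N"),
      summarise_par(cni_est[, "I"], true[["I"]], "cni", "I"),
      summarise_par(can_est$C_can, can_truth[["C_can"]], "can", "C_can"),
      summarise_par(can_est$A_can, can_truth[["A_can"]], "can", "A_can"),
      summarise_par(can_est$N_can, can_truth[["N_can"]], "can", "N_can")
    )
  }) -> out
  class(out) <- c("recovery_study", class(out))
  out
}

#' @rdname run_recovery_study
#' @param object A `recovery_study`.
#' @param ... Unused.
#' @export
autoplot.recovery_study <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$items_per_category, y = .data$rmse,
                               colour = .data$parameter,
                               linetype = .data$framework)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "items per category", y = "RMSE") +
    ggplot2::theme_minimal()
}
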