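#' Configuration for the synthetic cohort generator
#'
#' Defines the generative model used throughout the simulation studies: a
#' standard-normal latent chronic-stress score drives (a) the PSS-10 total
#' via `round(clip(pss_mean + pss_sd * stress, 0, 40))` and (b), through the
#' `coupling` slopes (logit units per SD of stress), the participant's CNI
#' decision parameters, drawn on the logit scale around `base_mean` with
#' between-participant SD `base_sd`. All couplings default to 0: stress and
#' moral-decision parameters are independent, the null regime against which
#' Type I error is assessed.
#'
#' @param n_participants Cohort size (default 208).
#' @param items_per_category Scenarios per battery category (default 6).
#' @param coupling Named numeric `c(C=, N=, I=)`: logit-scale slope of each
#'   parameter on the stress latent (default all 0).
#' @param base_mean Named logit-scale means of C, N, I; defaults
#'   `qlogis(c(0.2, 0.25, 0.41))`.
#' @param base_sd Named logit-scale between-participant SDs (default 0.5).
#' @param likert_noise_sd SD of the latent rating noise (default 1; at 1 the
#'   recoded accept rate equals the binary cell probability exactly).
#' @param likert_thresholds Five strictly increasing cutpoints mapping the
#'   latent acceptability to ratings 1-6; the third cutpoint of the default
#'   `c(-1.8, -0.8, 0, 0.8, 1.8)` is 0 so the 3/4 boundary coincides with the
#'   binary accept/reject boundary.
#' @param pss_mean,pss_sd Mean and SD of the PSS-10 total (defaults 12.15 and
#'   6.84).
#' @param include_pss14 Also generate 14-item PSS responses (default FALSE).
#' @param covariate_model List with elements `gender_prop_female`, `age_mean`,
#'   `age_sd`, `age_range`, `mc_key` (13 binary), `mc_endorse` (13 rates),
#'   `acute_stress_rate`, `attention_fail_rate`.
#' @param seed Default seed used by the generator functions when they are not
#'   given one explicitly.
#' @param replicates Default replicate count for the simulation studies.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 50, seed = 1)
sim_config <- function(n_participants = 208,
                       items_per_category = 6,
                       coupling = c(C = 0, N = 0, I = 0),
                       base_mean = qlogis(c(C = 0.2, N = 0.25, I = 0.41)),
                       base_sd = c(C = 0.5, N = 0.5, I = 0.5),
                       likert_noise_sd = 1,
                       likert_thresholds = c(-1.8, -0.8, 0, 0.8, 1.8),
                       pss_mean = 12.15,
                       pss_sd = 6.84,
                       include_pss14 = FALSE,
                       covariate_model = list(),
                       seed = NULL,
                       replicates = 100) {
  cov_defaults <- list(
    gender_prop_female = 0.567,
    age_mean = 32.07, age_sd = 12.35, age_range = c(17, 89),
    mc_key = rep_len(c(1L, 0L), 13),
    mc_endorse = rep(0.5, 13),
    acute_stress_rate = 0, attention_fail_rate = 0
  )
  unknown <- setdiff(names(covariate_model), names(cov_defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown covariate_model key(s): %s.", paste(unknown, collapse = ", ")))
  }
  covariate_model <- modifyList(cov_defaults, covariate_model)

  cfg <- list(
    n_participants = as.integer(n_participants),
    items_per_category = as.integer(items_per_category),
    coupling = coupling, base_mean = base_mean, base_sd = base_sd,
    likert_noise_sd = likert_noise_sd, likert_thresholds = likert_thresholds,
    pss_mean = pss_mean, pss_sd = pss_sd, include_pss14 = include_pss14,
    covariate_model = covariate_model,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    replicates = as.integer(replicates)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg A `sim_config` list to validate.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config") || is.list(cfg))
  if (cfg$n_participants < 1) abort("n_participants must be >= 1.")
  if (cfg$items_per_category < 1) abort("items_per_category must be >= 1.")
  for (nm in c("coupling", "base_mean", "base_sd")) {
    v <- cfg[[nm]]
    if (length(v) != 3 || !all(c("C", "N", "I") %in% names(v))) {
      abort(sprintf("`%s` must be a named numeric vector with elements C, N, I.", nm))
    }
  }
  if (any(cfg$base_sd < 0)) abort("base_sd must be nonnegative.")
  if (cfg$likert_noise_sd < 0) abort("likert_noise_sd must be nonnegative.")
  thr <- cfg$likert_thresholds
  if (length(thr) != 5 || any(diff(thr) <= 0)) {
    abort("likert_thresholds must be 5 strictly increasing cutpoints.")
  }
  if (cfg$pss_sd < 0) abort("pss_sd must be nonnegative.")
  cm <- cfg$covariate_model
  if (length(cm$mc_key) != 13 || length(cm$mc_endorse) != 13) {
    abort("mc_key and mc_endorse must have 13 elements.")
  }
  if (cfg$replicates < 1) abort("replicates must be >= 1.")
  cfg
}

# Decomposes integer PSS totals into per-item scored values (0..4) summing
# exactly to the total: greedy even spread, remainder on the early items.
# Returns the *raw* item responses, i.e. reverse-keyed items are flipped so
# that score_pss() recovers the total.
#' @noRd
decompose_pss <- function(totals, n_items, reverse_items) {
  base <- totals %/% n_items
  rem <- totals %% n_items
  scored <- outer(base, rep(1, n_items)) +
    outer(rem, seq_len(n_items), FUN = ">=") * 1
  raw <- scored
  raw[, reverse_items] <- 4 - scored[, reverse_items]
  storage.mode(raw) <- "integer"
  raw
}

#' Draw a synthetic participant cohort with known decision parameters
#'
#' Generates one participant table holding covariates (gender, age, PSS
#' items, social-desirability items, screening flags) together with the
#' generating truth (`stress_latent`, `C_true`, `N_true`, `I_true`). PSS item
#' scores are decomposed deterministically from the total (greedy even
#' spread) and respect the reverse keying, so [score_pss()] recovers the
#' generated total exactly.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; `NULL` (default) falls back to `config$seed`,
#'   and if that is also `NULL` the ambient RNG state is used.
#' @return A tibble with one row per participant; use
#'   [participant_records()] / [truth_table()] to split observable columns
#'   from the truth.
#' @export
draw_participants <- function(config, seed = NULL) {
  config <- validate_sim_config(config)
  seed <- seed %||% config$seed
  with_seed_or_ambient(seed, {
    n <- config$n_participants
    cm <- config$covariate_model
    stress <- rnorm(n)
    pss_total <- as.integer(round(pmin(pmax(
      config$pss_mean + config$pss_sd * stress, 0), 40)))
    pss_items <- decompose_pss(pss_total, 10, pss_reverse_items(10))
    colnames(pss_items) <- paste0("pss10_", 1:10)

    logit_par <- function(p) {
      plogis(config$base_mean[[p]] + config$coupling[[p]] * stress +
               rnorm(n, 0, config$base_sd[[p]]))
    }
    C_true <- logit_par("C"); N_true <- logit_par("N"); I_true <- logit_par("I")

    gender <- ifelse(rbinom(n, 1, cm$gender_prop_female) == 1, "female", "male")
    age <- as.integer(round(pmin(pmax(rnorm(n, cm$age_mean, cm$age_sd),
                                      cm$age_range[1]), cm$age_range[2])))
    mc <- matrix(rbinom(n * 13, 1, rep(cm$mc_endorse, each = n)), nrow = n)
    colnames(mc) <- paste0("mc_", 1:13)

    out <- tibble::tibble(
      participant_id = sprintf("p%04d", seq_len(n)),
      gender = gender, age = age
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(pss_items))
    if (config$include_pss14) {
      total14 <- as.integer(round(pmin(pmax(
        1.4 * (config$pss_mean + config$pss_sd * stress), 0), 56)))
      p14 <- decompose_pss(total14, 14, pss_reverse_items(14))
      colnames(p14) <- paste0("pss14_", 1:14)
      out <- dplyr::bind_cols(out, tibble::as_tibble(p14))
    }
    out <- dplyr::bind_cols(out, tibble::as_tibble(mc))
    dplyr::mutate(
      out,
      acute_stress = rbinom(n, 1, cm$acute_stress_rate),
      attention_pass = 1L - rbinom(n, 1, cm$attention_fail_rate),
      stress_latent = stress,
      C_true = C_true, N_true = N_true, I_true = I_true
    )
  })
}

#' @rdname draw_participants
#' @param participants Output of [draw_participants()].
#' @export
participant_records <- function(participants) {
  dplyr::select(participants, -dplyr::any_of(c("stress_latent", "C_true",
                                               "N_true", "I_true")))
}

#' @rdname draw_participants
#' @export
truth_table <- function(participants) {
  dplyr::select(participants, "participant_id", "stress_latent",
                "C_true", "N_true", "I_true")
}

# Per-item acceptance probability implied by each participant's tree
# parameters and the item's category; returns a vector aligned with the
# expanded (participant x item) grid.
#' @noRd
item_probabilities <- function(participants, battery) {
  probs <- as.matrix(cni_predict(participants$C_true, participants$N_true,
                                 participants$I_true))
  cat_idx <- match(battery$category, DILEMMA_CATEGORIES)
  n <- nrow(participants); m <- nrow(battery)
  probs[cbind(rep(seq_len(n), each = m), rep(cat_idx, times = n))]
}

#' Simulate binary accept/reject responses from true CNI parameters
#'
#' Each item is accepted with the probability the participant's `(C, N, I)`
#' tree assigns to the item's category.
#'
#' @param participants Cohort tibble from [draw_participants()] (must carry
#'   the truth columns).
#' @param battery Battery definition from [dilemma_battery()].
#' @param seed Integer seed or `NULL` for the ambient RNG.
#' @return A long response tibble: `participant_id`, `item_id`, `category`,
#'   `accept`.
#' @export
sample_binary_responses <- function(participants, battery, seed = NULL) {
  require_columns(participants, c("participant_id", "C_true", "N_true", "I_true"),
                  "participants")
  validate_battery(battery)
  with_seed_or_ambient(seed, {
    p <- item_probabilities(participants, battery)
    n <- nrow(participants); m <- nrow(battery)
    tibble::tibble(
      participant_id = rep(participants$participant_id, each = m),
      item_id = rep(battery$item_id, times = n),
      category = rep(battery$category, times = n),
      accept = rbinom(n * m, 1, p)
    )
  })
}

#' Simulate 1-6 Likert ratings from true CNI parameters
#'
#' A probit latent-variable model: the latent acceptability for an item is
#' \eqn{\Phi^{-1}(p) + \epsilon}, \eqn{\epsilon \sim N(0, \sigma)} with `p`
#' the tree cell probability and `sigma = likert_noise_sd`; the latent value
#' is cut at the five thresholds into ratings 1-6. With the default
#' thresholds (third cutpoint 0) and `sigma = 1`, the recoded accept
#' indicator (`rating >= 4`) is Bernoulli with success probability exactly
#' `p`, so dichotomized analyses see precisely the binary tree; as
#' `sigma -> 0` the rating deterministically agrees with the side of 0.5 on
#' which `p` falls.
#'
#' @inheritParams sample_binary_responses
#' @param config A [sim_config()] (supplies noise SD and thresholds).
#' @return A long response tibble: `participant_id`, `item_id`, `category`,
#'   `rating`.
#' @export
sample_likert_responses <- function(participants, battery, config, seed = NULL) {
  require_columns(participants, c("participant_id", "C_true", "N_true", "I_true"),
                  "participants")
  validate_battery(battery)
  config <- validate_sim_config(config)
  with_seed_or_ambient(seed, {
    p <- pmin(pmax(item_probabilities(participants, battery), 1e-12), 1 - 1e-12)
    n <- nrow(participants); m <- nrow(battery)
    latent <- qnorm(p) + rnorm(n * m, 0, config$likert_noise_sd)
    rating <- findInterval(latent, config$likert_thresholds) + 1L
    tibble::tibble(
      participant_id = rep(participants$participant_id, each = m),
      item_id = rep(battery$item_id, times = n),
      category = rep(battery$category, times = n),
      rating = rating
    )
  })
}

#' Simulate a complete cohort (participants, battery, responses)
#'
#' Convenience wrapper combining [draw_participants()],
#' [dilemma_battery()], and one of the response samplers, with stage-wise
#' child seeds derived from `seed` via [child_seed()].
#'
#' @param config A [sim_config()].
#' @param response_mode `"likert"` (default) or `"binary"`.
#' @param seed Integer master seed; `NULL` falls back to `config$seed`.
#' @return A list with elements `participants`, `battery`, `responses`.
#' @export
simulate_cohort <- function(config, response_mode = c("likert", "binary"),
                            seed = NULL) {
  response_mode <- match.arg(response_mode)
  config <- validate_sim_config(config)
  seed <- seed %||% config$seed
  battery <- dilemma_battery(config$items_per_category)
  participants <- draw_participants(config, seed = child_seed(seed, "participants"))
  responses <- if (response_mode == "binary") {
    sample_binary_responses(participants, battery,
                            seed = child_seed(seed, "responses"))
  } else {
    sample_likert_responses(participants, battery, config,
                            seed = child_seed(seed, "responses"))
  }
  list(participants = participants, battery = battery, responses = responses)
}
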