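#' Recode a 1-6 acceptability rating as a binary accept/reject decision
#'
#' Ratings of 4-6 indicate approval of the described action, 1-3 disapproval.
#'
#' @param rating Integer vector of ratings in 1..6.
#' @return Integer vector of the same length: 1 = accept, 0 = reject.
#' @export
#' @examples
#' recode_rating(1:6)
recode_rating <- function(rating) {
  assert_numeric_in(rating, 1, 6, "rating", integer = TRUE)
  as.integer(rating >= 4)
}

#' Default reverse-keyed item positions for the Perceived Stress Scale
#'
#' Standard instrument keying: the positively worded items are reverse-scored
#' (`x -> 4 - x`) before summation.
#'
#' @param version PSS version, 10 or 14 items.
#' @return Integer vector of item positions.
#' @export
pss_reverse_items <- function(version = 10) {
  version <- match.arg(as.character(version), c("10", "14"))
  if (version == "10") c(4L, 5L, 7L, 8L) else c(4L, 5L, 6L, 7L, 9L, 10L, 13L)
}

#' Score the Perceived Stress Scale (PSS-10 or PSS-14)
#'
#' Items are rated 0 (never) to 4 (very often); the configured positive items
#' are reverse-scored and all items summed. The 10-item total lies in
#' \[0, 40\], the 14-item total in \[0, 56\]; higher totals indicate greater
#' perceived chronic stress over the past month.
#'
#' @param items Integer vector of item responses in 0..4 (length 10 or 14,
#'   matching `version`).
#' @param version 10 (default) or 14.
#' @param reverse_items Positions of reverse-scored items; defaults to the
#'   standard keying via [pss_reverse_items()]. Use `integer(0)` for no
#'   reversal.
#' @return The integer total score.
#' @export
#' @examples
#' score_pss(rep(2, 10))
score_pss <- function(items, version = 10, reverse_items = NULL) {
  version <- as.integer(match.arg(as.character(version), c("10", "14")))
  if (length(items) != version) {
    abort(sprintf("PSS-%d scoring needs exactly %d items; got %d.",
                  version, version, length(items)))
  }
  assert_numeric_in(items, 0, 4, "items", integer = TRUE)
  reverse_items <- reverse_items %||% pss_reverse_items(version)
  if (length(reverse_items) > 0) {
    assert_numeric_in(reverse_items, 1, version, "reverse_items", integer = TRUE)
    items[reverse_items] <- 4L - items[reverse_items]
  }
  as.integer(sum(items))
}

#' Score the abbreviated 13-item social-desirability scale
#'
#' Counts yes/no responses that match the keyed (socially desirable)
#' direction; higher totals reflect greater reliance on social approval.
#'
#' @param responses Binary vector of 13 responses (1 = yes, 0 = no).
#' @param key Binary vector of 13 keyed directions.
#' @return Integer total in 0..13.
#' @export
score_social_desirability <- function(responses, key) {
  if (length(responses) != 13 || length(key) != 13) {
    abort("social-desirability scoring needs 13 responses and a 13-element key.")
  }
  assert_numeric_in(responses, 0, 1, "responses", integer = TRUE)
  assert_numeric_in(key, 0, 1, "key", integer = TRUE)
  as.integer(sum(responses == key))
}

#' Cronbach's alpha for a set of scale items
#'
#' Descriptive internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of the total)`.
#' Reported as a one-line descriptive alongside scale totals; no further
#' reliability modelling is done.
#'
#' @param items A numeric matrix or data frame, one column per item.
#' @return Cronbach's alpha.
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (ncol(m) < 2 || nrow(m) < 2) abort("need >= 2 items and >= 2 respondents.")
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) abort("zero variance in the total score.")
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Screen participants for analysis eligibility
#'
#' Applies the exclusion rules in order: (1) recent acute stress
#' (`acute_stress = 1`), (2) incomplete dilemma battery (fewer than `n_items`
#' distinct items answered), (3) failed attention check
#' (`attention_pass = 0`). Each excluded participant is logged with the first
#' matching reason.
#'
#' @param records Participant covariate tibble with columns `participant_id`,
#'   `acute_stress`, `attention_pass`.
#' @param responses Long response tibble with columns `participant_id`,
#'   `item_id`.
#' @param n_items Number of battery items required for completeness
#'   (default 24).
#' @return A tibble with columns `participant_id`, `retained` (logical) and
#'   `reason` (`NA` when retained; otherwise one of `"acute_stress"`,
#'   `"incomplete"`, `"attention_fail"`).
#' @export
screen_participants <- function(records, responses, n_items = 24) {
  require_columns(records, c("participant_id", "acute_stress", "attention_pass"),
                  "records")
  require_columns(responses, c("participant_id", "item_id"), "responses")
  answered <- dplyr::summarise(
    dplyr::group_by(responses, .data$participant_id),
    n_answered = dplyr::n_distinct(.data$item_id),
    .groups = "drop"
  )
  out <- dplyr::left_join(
    dplyr::select(records, "participant_id", "acute_stress", "attention_pass"),
    answered, by = "participant_id"
  )
  out$n_answered[is.na(out$n_answered)] <- 0L
  reason <- dplyr::case_when(
    out$acute_stress == 1 ~ "acute_stress",
    out$n_answered < n_items ~ "incomplete",
    out$attention_pass == 0 ~ "attention_fail",
    TRUE ~ NA_character_
  )
  tibble::tibble(
    participant_id = out$participant_id,
    retained = is.na(reason),
    reason = reason
  )
}

#' Median-split a score into high and low groups
#'
#' Scores strictly above the sample median are labelled `high`, strictly
#' below `low`; scores equal to the median go to the side named by `tie`
#' (default `"low"`). This is the dichotomization practice whose statistical
#' cost the simulation studies in this package quantify.
#'
#' @param data A data frame of participants.
#' @param score Column holding the continuous score (tidy-eval).
#' @param tie `"low"` (default) or `"high"`: side receiving scores equal to
#'   the median.
#' @return `data` with an added factor column `split_group` (levels `low`,
#'   `high`). The per-group summary (n, mean, sd) is attached as the
#'   `"summary"` attribute.
#' @export
#' @examples
#' df <- tibble::tibble(id = 1:4, pss = c(1, 2, 3, 4))
#' median_split(df, pss)
median_split <- function(data, score, tie = c("low", "high")) {
  tie <- match.arg(tie)
  scores <- dplyr::pull(data, {{ score }})
  if (length(scores) < 2) abort("median_split needs at least 2 participants.")
  if (anyNA(scores)) abort("median_split scores contain missing values.")
  med <- median(scores)
  if (all(scores == scores[1])) {
    abort("all scores are equal; the median split is degenerate.")
  }
  group <- ifelse(scores > med, "high",
                  ifelse(scores < med, "low", tie))
  out <- dplyr::mutate(data, split_group = factor(group, levels = c("low", "high")))
  summary <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(split_group = out$split_group, score = scores),
                    .data$split_group),
    n = dplyr::n(),
    mean = mean(.data$score),
    sd = sd(.data$score),
    .groups = "drop"
  )
  attr(out, "summary") <- summary
  out
}
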