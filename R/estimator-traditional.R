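#' Traditional utilitarian acceptance score
#'
#' The traditional analysis reduces the battery to the trolley-style cell:
#' the proportion of accepted actions among the norm-prohibited,
#' benefits-outweigh-costs (`PB`) scenarios. Accepting reflects utilitarian,
#' rejecting deontological judgment.
#'
#' @param profiles Binary-mode profile tibble from [aggregate_profiles()].
#' @return A tibble with columns `participant_id` and `p_action` (the `PB`
#'   acceptance proportion, in \[0, 1\]).
#' @export
fit_traditional <- function(profiles) {
  require_columns(profiles, c("participant_id", "mode", "PB"), "profiles")
  if (any(profiles$mode != "binary")) {
    abort("the traditional score is defined on binary (accept/reject) profiles.")
  }
  tibble::tibble(
    participant_id = profiles$participant_id,
    p_action = profiles$PB
  )
}
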