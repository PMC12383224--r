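#' Process-dissociation decomposition of prohibited-norm dilemma responses
#'
#' The process-dissociation procedure uses only the two proscriptive-norm
#' cells: the *incongruent* cell (`PB`: benefits outweigh costs, so norms and
#' outcomes conflict) and the *congruent* cell (`PC`: costs outweigh
#' benefits, so norms and outcomes agree). From the two rejection rates it
#' separates a utilitarian-driven parameter `U` and a deontology-driven
#' parameter `D` via
#' \deqn{P(reject | congruent) = U + (1 - U) D, \quad
#'       P(reject | incongruent) = (1 - U) D,}
#' so that `U = p_c - p_i` and `D = p_i / (1 - U)`. With two parameters and
#' two observations the decomposition is exact: the forward model reproduces
#' the inputs to machine precision. `D` is undefined when `U = 1`.
#'
#' @param p_reject_congruent Rejection rate in congruent (`PC`) dilemmas,
#'   in \[0, 1\]. Vectorized.
#' @param p_reject_incongruent Rejection rate in incongruent (`PB`) dilemmas,
#'   in \[0, 1\]. Vectorized.
#' @return A tibble with columns `U`, `D`, and `d_defined` (`FALSE` where
#'   `U = 1`, in which case `D` is `NA` rather than silently dropped).
#' @export
#' @examples
#' pd_params(0.57, 0.38)
pd_params <- function(p_reject_congruent, p_reject_incongruent) {
  assert_numeric_in(p_reject_congruent, 0, 1, "p_reject_congruent")
  assert_numeric_in(p_reject_incongruent, 0, 1, "p_reject_incongruent")
  U <- p_reject_congruent - p_reject_incongruent
  d_defined <- U != 1
  D <- ifelse(d_defined, p_reject_incongruent / (1 - U), NA_real_)
  tibble::tibble(U = U, D = D, d_defined = d_defined)
}

#' Forward process-dissociation model
#'
#' Maps `U` and `D` back to the two rejection probabilities; the inverse of
#' [pd_params()].
#'
#' @param U Utilitarian-driven parameter, in \[-1, 1\]. Vectorized.
#' @param D Deontology-driven parameter (real, nonnegative; typically in
#'   \[0, 1\]). Vectorized.
#' @return A tibble with columns `p_reject_congruent` and
#'   `p_reject_incongruent`.
#' @export
#' @examples
#' pd_predict(0.19, 0.47)
pd_predict <- function(U, D) {
  assert_numeric_in(U, -1, 1, "U")
  if (!is.numeric(D) || anyNA(D) || any(D < 0)) {
    abort("`D` must be numeric and nonnegative.")
  }
  p_i <- (1 - U) * D
  tibble::tibble(
    p_reject_congruent = U + p_i,
    p_reject_incongruent = p_i
  )
}

#' Fit process-dissociation parameters for every participant in a profile table
#'
#' @param profiles Binary-mode profile tibble from [aggregate_profiles()].
#' @return A tibble with columns `participant_id`, `U`, `D`, `d_defined`.
#' @export
fit_pd <- function(profiles) {
  require_columns(profiles, c("participant_id", "mode", "PB", "PC"), "profiles")
  if (any(profiles$mode != "binary")) {
    abort("process dissociation is defined on binary (accept/reject) profiles.")
  }
  est <- pd_params(p_reject_congruent = 1 - profiles$PC,
                   p_reject_incongruent = 1 - profiles$PB)
  dplyr::bind_cols(tibble::tibble(participant_id = profiles$participant_id), est)
}
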