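#' Algebraic CAN decomposition of category profiles
#'
#' The CAN decomposition expresses the four per-category response values
#' \eqn{v_t} (acceptance proportions in binary mode, mean 1-6 ratings in
#' continuous mode) as three orthogonal contrasts, computed without
#' iterative fitting:
#' \deqn{C = ((v_{PB} + v_{AB}) - (v_{PC} + v_{AC})) / 2}
#' \deqn{N = ((v_{AB} + v_{AC}) - (v_{PB} + v_{PC})) / 2}
#' \deqn{A = (v_{PB} + v_{PC} + v_{AB} + v_{AC}) / 4}
#' `C` is consequence sensitivity (benefits-vs-costs contrast), `N` norm
#' sensitivity (prescriptive-vs-proscriptive contrast), and `A` the overall
#' action/inaction bias (grand mean; 0.5 is neutral on the binary scale, 3.5
#' on the 1-6 rating scale). On the binary scale `C, N` lie in \[-1, 1\] and
#' `A` in \[0, 1\]; on the continuous scale `C, N` lie in \[-5, 5\] and `A`
#' in \[1, 6\] (raw rating units, no renormalization).
#'
#' For noise-free profiles generated by [cni_predict()] the two frameworks
#' are bridged exactly: `C_can = C_cni`, `N_can = (1 - C_cni) * N_cni`, and
#' `A_can = C_cni/2 + (1 - C_cni) N_cni / 2 + (1 - C_cni)(1 - N_cni)(1 - I_cni)`.
#'
#' @param v_PB,v_PC,v_AB,v_AC Per-category values on a common scale.
#'   Vectorized.
#' @param scale `"binary"` (values in \[0, 1\]) or `"continuous"` (values in
#'   \[1, 6\]).
#' @return A tibble with columns `C_can`, `A_can`, `N_can`, `scale`.
#' @export
#' @examples
#' can_params(0.56, 0.36, 0.76, 0.56, scale = "binary")
can_params <- function(v_PB, v_PC, v_AB, v_AC, scale = c("binary", "continuous")) {
  scale <- match.arg(scale)
  lims <- if (scale == "binary") c(0, 1) else c(1, 6)
  for (v in list(v_PB, v_PC, v_AB, v_AC)) {
    assert_numeric_in(v, lims[1], lims[2], sprintf("%s-scale category values", scale))
  }
  tibble::tibble(
    C_can = ((v_PB + v_AB) - (v_PC + v_AC)) / 2,
    A_can = (v_PB + v_PC + v_AB + v_AC) / 4,
    N_can = ((v_AB + v_AC) - (v_PB + v_PC)) / 2,
    scale = scale
  )
}

#' Compute CAN parameters for every participant in a profile table
#'
#' The scale tag is taken from the profile `mode`.
#'
#' @param profiles Profile tibble from [aggregate_profiles()] (either mode).
#' @return A tibble with columns `participant_id`, `C_can`, `A_can`, `N_can`,
#'   `scale`.
#' @export
fit_can <- function(profiles) {
  require_columns(profiles, c("participant_id", "mode", DILEMMA_CATEGORIES),
                  "profiles")
  mode <- unique(profiles$mode)
  if (length(mode) != 1) abort("profiles mix binary and continuous modes.")
  est <- can_params(profiles$PB, profiles$PC, profiles$AB, profiles$AC,
                    scale = mode)
  dplyr::bind_cols(tibble::tibble(participant_id = profiles$participant_id), est)
}
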