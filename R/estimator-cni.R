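#' Predicted acceptance probabilities under the CNI processing tree
#'
#' The CNI model is a multinomial processing tree in which a decision-maker
#' first responds to consequences with probability `C`, otherwise to norms
#' with probability `N`, and otherwise follows a generalized inaction
#' preference `I`. For the four battery categories this gives
#' \deqn{p_{PB} = C + (1-C)(1-N)(1-I)}
#' \deqn{p_{PC} = (1-C)(1-N)(1-I)}
#' \deqn{p_{AB} = C + (1-C)N + (1-C)(1-N)(1-I)}
#' \deqn{p_{AC} = (1-C)N + (1-C)(1-N)(1-I)}
#' where each `p` is the probability of *accepting* the action.
#'
#' @param C,N,I Tree parameters in \[0, 1\]. Vectorized.
#' @return A tibble with columns `p_PB`, `p_PC`, `p_AB`, `p_AC`.
#' @export
#' @examples
#' cni_predict(0.2, 0.25, 0.4)
cni_predict <- function(C, N, I) {
  assert_numeric_in(C, 0, 1, "C")
  assert_numeric_in(N, 0, 1, "N")
  assert_numeric_in(I, 0, 1, "I")
  base <- (1 - C) * (1 - N) * (1 - I)  # neither consequences nor norms drive; action chosen
  norm <- (1 - C) * N
  clamp01 <- function(x) pmin(pmax(x, 0), 1)  # guard float overshoot at cell sums of 1
  tibble::tibble(
    p_PB = clamp01(C + base),
    p_PC = clamp01(base),
    p_AB = clamp01(C + norm + base),
    p_AC = clamp01(norm + base)
  )
}

#' Algebraic inversion of the CNI tree
#'
#' Solves the tree equations for `(C, N, I)` from four acceptance
#' probabilities:
#' `C = ((p_PB - p_PC) + (p_AB - p_AC)) / 2`,
#' `N = ((p_AB - p_PB) + (p_AC - p_PC)) / (2 (1 - C))`,
#' `I = 1 - p_PC / ((1 - C)(1 - N))`.
#' A profile is *feasible* only if the recovered parameters lie in
#' \[0, 1\]^3 and the forward model reproduces all four inputs (the tree has
#' 3 parameters for 4 cells, so not every profile lies on the model
#' manifold). Division-by-zero branches yield the infeasible marker with
#' `NA` components rather than an error. Used as the algebraic initializer
#' for [cni_fit()] and as an exact oracle on noise-free profiles.
#'
#' @param p_PB,p_PC,p_AB,p_AC Acceptance probabilities in \[0, 1\].
#' @param tol Tolerance for the forward-model reproduction check.
#' @return A one-row tibble with columns `C`, `N`, `I`, `feasible`.
#' @export
#' @examples
#' cni_invert(0.56, 0.36, 0.76, 0.56)
cni_invert <- function(p_PB, p_PC, p_AB, p_AC, tol = 1e-8) {
  p <- c(p_PB, p_PC, p_AB, p_AC)
  stopifnot(length(p) == 4)
  assert_numeric_in(p, 0, 1, "probabilities")
  C <- ((p[1] - p[2]) + (p[3] - p[4])) / 2
  N <- NA_real_
  I <- NA_real_
  feasible <- FALSE
  if (is.finite(C) && C >= 0 && C <= 1 && (1 - C) > 0) {
    N <- ((p[3] - p[1]) + (p[4] - p[2])) / (2 * (1 - C))
    if (is.finite(N) && N >= 0 && N <= 1 && (1 - N) > 0) {
      I <- 1 - p[2] / ((1 - C) * (1 - N))
      if (is.finite(I) && I >= 0 && I <= 1) {
        pred <- unlist(cni_predict(C, N, I), use.names = FALSE)
        feasible <- max(abs(pred - p)) < tol
      }
    }
  }
  tibble::tibble(C = C, N = N, I = I, feasible = feasible)
}

# Tree cell probabilities as a bare vector (PB, PC, AB, AC); the hot path
# for optimization, so no tibble construction here.
#' @noRd
cni_cells <- function(theta) {
  C <- theta[1]; N <- theta[2]; I <- theta[3]
  base <- (1 - C) * (1 - N) * (1 - I)
  norm <- (1 - C) * N
  c(C + base, base, C + norm + base, norm + base)
}

# Product-binomial log-likelihood of CNI parameters given per-category
# accept counts k of n; probabilities clipped away from 0/1 so boundary
# parameter values remain evaluable.
#' @noRd
cni_loglik <- function(theta, k, n, clip = 1e-9) {
  p <- pmin(pmax(cni_cells(theta), clip), 1 - clip)
  sum(k * log(p) + (n - k) * log1p(-p))
}

# G-squared against the saturated model, with 0*log(0) = 0.
#' @noRd
cni_gsq <- function(theta, k, n) {
  p <- cni_cells(theta)
  term <- function(obs, exp_) {
    out <- numeric(length(obs))
    nz <- obs > 0
    out[nz] <- obs[nz] * log(obs[nz] / exp_[nz])
    out
  }
  2 * sum(term(k, n * p) + term(n - k, n * (1 - p)))
}

#' Maximum-likelihood fit of the CNI processing tree to one participant
#'
#' Maximizes the product-binomial likelihood of the four per-category accept
#' counts over `(C, N, I)` in the unit cube, using L-BFGS-B multi-start: the
#' algebraic initializer from [cni_invert()] on the observed proportions
#' (when available) plus `n_starts` seeded uniform restarts. Fit is assessed
#' by the likelihood-ratio statistic G-squared against the saturated model
#' on `df = 1` (4 cells, 3 parameters); participants with `fit_p < 0.05` are
#' flagged for exclusion (a small goodness-of-fit p-value indicates misfit).
#' Estimates within `1e-6` of the cube boundary are flagged; in particular
#' `C` at 1 leaves `N` and `I` unidentified.
#'
#' @param k Integer vector of accept counts for categories `PB, PC, AB, AC`
#'   (in that order, or named).
#' @param n Integer vector of trial counts per category (recycled if
#'   length 1).
#' @param n_starts Number of seeded uniform restarts (default 20).
#' @param restart_seed Seed for the restart draws (fixed default keeps fits
#'   deterministic).
#' @return An object of class `cni_fit`: a list with elements `C`, `N`, `I`,
#'   `loglik`, `gsq`, `df`, `fit_p`, `excluded`, `boundary`, `note`, `k`,
#'   `n`, `convergence`. Use [tidy()] / [glance()] for tibble views.
#' @export
#' @examples
#' fit <- cni_fit(c(4, 2, 5, 3), 6)
#' glance(fit)
cni_fit <- function(k, n, n_starts = 20, restart_seed = 20240603) {
  if (!is.null(names(k))) k <- k[DILEMMA_CATEGORIES]
  k <- as.numeric(k)
  if (length(n) == 1) n <- rep(n, 4)
  n <- as.numeric(n)
  if (length(k) != 4 || length(n) != 4 || anyNA(k) || anyNA(n)) {
    abort("cni_fit needs accept counts and trial counts for all four categories.")
  }
  if (any(n < 1) || any(k < 0) || any(k > n)) {
    abort("counts must satisfy 0 <= k <= n with n >= 1 in every category.")
  }

  starts <- list()
  inv <- cni_invert(k[1] / n[1], k[2] / n[2], k[3] / n[3], k[4] / n[4])
  algebraic <- c(inv$C, inv$N, inv$I)
  algebraic[!is.finite(algebraic)] <- 0.5
  starts[[1]] <- pmin(pmax(algebraic, 1e-3), 1 - 1e-3)
  restarts <- with_seed_or_ambient(restart_seed,
                                   matrix(runif(3 * n_starts), ncol = 3))
  for (i in seq_len(n_starts)) starts[[i + 1]] <- restarts[i, ]

  best <- NULL
  any_converged <- FALSE
  for (s in starts) {
    res <- tryCatch(
      optim(s, cni_loglik, k = k, n = n,
            method = "L-BFGS-B", lower = 0, upper = 1,
            control = list(fnscale = -1, factr = 1e4, pgtol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_converged <- TRUE
    if (is.null(best) || res$value > best$value) best <- res
  }
  if (is.null(best) || !any_converged) {
    abort(sprintf(
      "CNI optimizer failed to converge from any of %d starts (counts k = %s, n = %s).",
      length(starts), paste(k, collapse = ","), paste(n, collapse = ",")))
  }

  theta <- pmin(pmax(best$par, 0), 1)
  gsq <- cni_gsq(theta, k, n)
  fit_p <- pchisq(gsq, df = 1, lower.tail = FALSE)
  eps <- 1e-6
  at_bound <- theta < eps | theta > 1 - eps
  note <- NA_character_
  if (theta[1] > 1 - eps) {
    note <- "C at upper bound: N and I unidentified"
  } else if (any(at_bound)) {
    note <- sprintf("boundary estimate for %s",
                    paste(c("C", "N", "I")[at_bound], collapse = ", "))
  }

  structure(
    list(C = theta[1], N = theta[2], I = theta[3],
         loglik = best$value, gsq = gsq, df = 1L, fit_p = fit_p,
         excluded = fit_p < 0.05, boundary = any(at_bound), note = note,
         k = k, n = n, convergence = best$convergence),
    class = "cni_fit"
  )
}

#' @export
print.cni_fit <- function(x, ...) {
  cat("CNI processing-tree fit\n")
  cat(sprintf("  C = %.4f, N = %.4f, I = %.4f%s\n", x$C, x$N, x$I,
              if (x$boundary) " (boundary)" else ""))
  cat(sprintf("  G^2 = %.4g on %d df, p = %.4f%s\n", x$gsq, x$df, x$fit_p,
              if (x$excluded) " [flagged for exclusion]" else ""))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @rdname cni_fit
#' @param x A `cni_fit` object.
#' @param ... Unused.
#' @export
tidy.cni_fit <- function(x, ...) {
  tibble::tibble(
    term = c("C", "N", "I"),
    estimate = c(x$C, x$N, x$I),
    boundary = c(x$C, x$N, x$I) < 1e-6 | c(x$C, x$N, x$I) > 1 - 1e-6
  )
}

#' @rdname cni_fit
#' @export
glance.cni_fit <- function(x, ...) {
  tibble::tibble(
    C = x$C, N = x$N, I = x$I,
    loglik = x$loglik, gsq = x$gsq, df = x$df, fit_p = x$fit_p,
    excluded = x$excluded, boundary = x$boundary, note = x$note
  )
}

#' Fit the CNI tree to every participant in a profile table
#'
#' Participants whose counts cannot be fitted (optimizer failure) are
#' reported with `error` set and numeric columns `NA`, mirroring how
#' unfittable response patterns are tallied separately from poor-fit
#' exclusions.
#'
#' @param profiles Binary-mode profile tibble from [aggregate_profiles()].
#' @inheritParams cni_fit
#' @return A tibble with one row per participant: `participant_id`, `C_cni`,
#'   `N_cni`, `I_cni`, `gsq`, `df`, `fit_p`, `excluded`, `boundary`, `note`,
#'   `error`.
#' @export
fit_cni <- function(profiles, n_starts = 20, restart_seed = 20240603) {
  require_columns(profiles, c("participant_id", "mode", DILEMMA_CATEGORIES,
                              paste0("n_", DILEMMA_CATEGORIES)), "profiles")
  if (any(profiles$mode != "binary")) {
    abort("the CNI tree is fitted to binary (accept/reject) profiles.")
  }
  purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    n <- unlist(profiles[i, paste0("n_", DILEMMA_CATEGORIES)], use.names = FALSE)
    k <- round(unlist(profiles[i, DILEMMA_CATEGORIES], use.names = FALSE) * n)
    fit <- tryCatch(cni_fit(k, n, n_starts = n_starts, restart_seed = restart_seed),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      tibble::tibble(
        participant_id = profiles$participant_id[i],
        C_cni = NA_real_, N_cni = NA_real_, I_cni = NA_real_,
        gsq = NA_real_, df = NA_integer_, fit_p = NA_real_,
        excluded = NA, boundary = NA, note = NA_character_,
        error = conditionMessage(fit)
      )
    } else {
      tibble::tibble(
        participant_id = profiles$participant_id[i],
        C_cni = fit$C, N_cni = fit$N, I_cni = fit$I,
        gsq = fit$gsq, df = fit$df, fit_p = fit$fit_p,
        excluded = fit$excluded, boundary = fit$boundary, note = fit$note,
        error = NA_character_
      )
    }
  })
}
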