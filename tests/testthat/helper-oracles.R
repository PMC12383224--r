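# Independent oracles used across tests. These re-derive results from first
# principles (tree enumeration, grid search, textbook formulas, brute-force
# simulation) and never call the code paths they check.

# Acceptance probability per category derived by enumerating the three
# branches of the processing tree: with probability C the consequence branch
# fires (accept iff benefits outweigh costs); otherwise with probability N
# the norm branch fires (accept iff the norm favours action); otherwise the
# generalized preference branch accepts with probability 1 - I.
oracle_tree_prob <- function(C, N, I, category) {
  benefits <- substr(category, 2, 2) == "B"
  norm_favours <- substr(category, 1, 1) == "A"
  C * as.numeric(benefits) +
    (1 - C) * N * as.numeric(norm_favours) +
    (1 - C) * (1 - N) * (1 - I)
}

oracle_tree_cells <- function(C, N, I) {
  vapply(c("PB", "PC", "AB", "AC"), function(ct) oracle_tree_prob(C, N, I, ct),
         numeric(1))
}

# Product-binomial log-likelihood written independently of the package
# (same 1e-9 clipping convention so boundary values are comparable).
oracle_loglik <- function(theta, k, n) {
  p <- oracle_tree_cells(theta[1], theta[2], theta[3])
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  sum(k * log(p) + (n - k) * log(1 - p))
}

# Exhaustive grid search over [0,1]^3 for the best product-binomial
# log-likelihood. Returns a function ll(k, n) -> max grid log-likelihood;
# the (large) grid log-probability matrices are built once per call to
# make_grid_oracle and shared across fixtures.
make_grid_oracle <- function(step) {
  g <- seq(0, 1, by = step)
  m <- length(g)
  C <- rep(g, times = m^2)
  N <- rep(rep(g, each = m), times = m)
  I <- rep(g, each = m^2)
  benefits <- c(1, 0, 1, 0)
  norm_favours <- c(0, 0, 1, 1)
  P <- matrix(0, length(C), 4)
  for (t in 1:4) {
    P[, t] <- C * benefits[t] + (1 - C) * N * norm_favours[t] +
      (1 - C) * (1 - N) * (1 - I)
  }
  clip <- 1e-9
  LP <- log(pmin(pmax(P, clip), 1 - clip))
  L1P <- log(pmin(pmax(1 - P, clip), 1 - clip))
  rm(P, C, N, I)
  function(k, n) {
    if (length(n) == 1) n <- rep(n, 4)
    max(LP %*% k + L1P %*% (n - k))
  }
}

# Per-category values of a tiny long response table computed by direct
# summation, no grouping machinery.
oracle_category_means <- function(responses, value_col) {
  cats <- c("PB", "PC", "AB", "AC")
  vapply(cats, function(ct) {
    mean(responses[[value_col]][responses$category == ct])
  }, numeric(1))
}

# A minimal valid cohort for pipeline-level tests.
make_test_cohort <- function(n = 40, seed = 101, coupling = c(C = 0, N = 0, I = 0),
                             ...) {
  cfg <- sim_config(n_participants = n, coupling = coupling, seed = seed, ...)
  simulate_cohort(cfg, seed = seed)
}
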