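test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_participants = 0), "n_participants")
  expect_error(sim_config(coupling = c(C = 0, N = 0)), "coupling")
  expect_error(sim_config(likert_thresholds = c(0, 1, 1, 2, 3)), "increasing")
  expect_error(sim_config(covariate_model = list(nope = 1)), "nope")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_participants = 30)
  a <- draw_participants(cfg, seed = 99)
  b <- draw_participants(cfg, seed = 99)
  expect_identical(a, b)
  ca <- simulate_cohort(cfg, seed = 42)
  cb <- simulate_cohort(cfg, seed = 42)
  expect_identical(ca, cb)
  cc <- simulate_cohort(cfg, seed = 43)
  expect_false(identical(ca$responses, cc$responses))
})

test_that("PSS items decompose totals exactly and respect keying and bounds", {
  totals <- 0:40
  raw <- moralcan:::decompose_pss(totals, 10, pss_reverse_items(10))
  expect_true(all(raw >= 0 & raw <= 4))
  rescored <- apply(raw, 1, score_pss)
  expect_equal(rescored, totals)

  cfg <- sim_config(n_participants = 300)
  parts <- draw_participants(cfg, seed = 1)
  tot <- score_pss_table(parts, 10)
  expect_true(all(tot >= 0 & tot <= 40))
  expect_true(all(as.matrix(parts[paste0("pss10_", 1:10)]) %in% 0:4))
})

test_that("null coupling leaves stress and true parameters uncorrelated", {
  cfg <- sim_config(n_participants = 2000)
  parts <- draw_participants(cfg, seed = 7)
  pss <- score_pss_table(parts, 10)
  for (par in c("C_true", "N_true", "I_true")) {
    expect_lt(abs(cor(pss, parts[[par]])), 0.05)
  }
})

test_that("positive coupling induces a positive stress-parameter association", {
  cfg <- sim_config(n_participants = 2000, coupling = c(C = 0.5, N = 0, I = 0))
  parts <- draw_participants(cfg, seed = 8)
  pss <- score_pss_table(parts, 10)
  expect_gt(cor(pss, parts$C_true, method = "spearman"), 0.2)
  expect_lt(abs(cor(pss, parts$N_true)), 0.05)
})

test_that("binary responses follow the tree probabilities", {
  # degenerate branch: pure consequence-driven decisions
  one <- tibble::tibble(participant_id = "p1", C_true = 1, N_true = 0.3,
                        I_true = 0.7)
  resp <- sample_binary_responses(one, dilemma_battery(), seed = 1)
  expect_true(all(resp$accept[resp$category %in% c("PB", "AB")] == 1))
  expect_true(all(resp$accept[resp$category %in% c("PC", "AC")] == 0))

  # calibration at (0.2, 0.25, 0.4) with 2500 items per category
  gen <- tibble::tibble(participant_id = "p1", C_true = 0.2, N_true = 0.25,
                        I_true = 0.4)
  big <- sample_binary_responses(gen, dilemma_battery(2500), seed = 2)
  rates <- oracle_category_means(big, "accept")
  expect_equal(unname(rates), c(0.56, 0.36, 0.76, 0.56), tolerance = 0.01 / 0.56)

  # bookkeeping: default battery gives 6 trials per category
  prof <- aggregate_profiles(resp, mode = "binary")
  expect_equal(unlist(prof[paste0("n_", c("PB", "PC", "AB", "AC"))],
                      use.names = FALSE), rep(6L, 4))
})

test_that("noise-free ratings land on the accept side implied by the cell probability", {
  cfg0 <- sim_config(likert_noise_sd = 0)
  hi <- tibble::tibble(participant_id = "p1", C_true = 0.01, N_true = 0.01,
                       I_true = 0.01)
  # strong action bias: all four cells have acceptance probability near 1
  resp <- sample_likert_responses(hi, dilemma_battery(), cfg0, seed = 3)
  expect_true(all(resp$rating >= 4))
  lo <- tibble::tibble(participant_id = "p1", C_true = 0.005, N_true = 0.005,
                       I_true = 0.99)
  # all cells near zero acceptance
  resp_lo <- sample_likert_responses(lo, dilemma_battery(), cfg0, seed = 3)
  expect_true(all(resp_lo$rating <= 3))
})

test_that("recoded default-noise ratings are calibrated to the cell probabilities", {
  cfg <- sim_config()
  gen <- tibble::tibble(participant_id = "p1", C_true = 0.2, N_true = 0.25,
                        I_true = 0.4)
  resp <- sample_likert_responses(gen, dilemma_battery(2500), cfg, seed = 4)
  resp$accept <- as.integer(resp$rating >= 4)
  rates <- oracle_category_means(resp, "accept")
  expect_equal(unname(rates), c(0.56, 0.36, 0.76, 0.56), tolerance = 0.02 / 0.36)
})

test_that("demographics follow the configured covariate model", {
  cfg <- sim_config(n_participants = 2000)
  parts <- draw_participants(cfg, seed = 9)
  expect_true(all(parts$age >= 17 & parts$age <= 89))
  expect_equal(mean(parts$gender == "female"), 0.567, tolerance = 0.05)
  expect_true(all(parts$acute_stress == 0))
  expect_true(all(parts$attention_pass == 1))
  cfg2 <- sim_config(n_participants = 500,
                     covariate_model = list(acute_stress_rate = 0.3))
  parts2 <- draw_participants(cfg2, seed = 10)
  expect_gt(mean(parts2$acute_stress), 0.2)
})
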