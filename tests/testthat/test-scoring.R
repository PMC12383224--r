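test_that("rating recode accepts exactly the 4-6 band", {
  expect_equal(recode_rating(1:6), c(0L, 0L, 0L, 1L, 1L, 1L))
  for (r in 1:6) expect_identical(recode_rating(r) == 1L, r >= 4)
  expect_error(recode_rating(0), "1")
  expect_error(recode_rating(7), "6")
  expect_error(recode_rating(4.5), "whole numbers")
})

test_that("PSS scoring reverses the keyed items and respects scale bounds", {
  expect_equal(score_pss(rep(0, 10), reverse_items = integer(0)), 0L)
  expect_equal(score_pss(rep(4, 10), reverse_items = integer(0)), 40L)
  # default reverse key {4,5,7,8}: six items keep 4, four become 0
  expect_equal(score_pss(rep(4, 10)), 24L)
  expect_equal(score_pss(rep(4, 14), version = 14), 4L * 7L)
  expect_error(score_pss(rep(1, 9)), "exactly 10")
  expect_error(score_pss(c(rep(1, 9), 5)), "\\[0, 4\\]")
})

test_that("PSS total is monotone in items according to their keying", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      items <- sample(0:3, 10, replace = TRUE)  # leave headroom for +1
      base <- score_pss(items)
      i <- sample(10, 1)
      bumped <- items
      bumped[i] <- bumped[i] + 1L
      delta <- score_pss(bumped) - base
      if (i %in% pss_reverse_items(10)) {
        expect_equal(delta, -1L)
      } else {
        expect_equal(delta, 1L)
      }
    }
  })
})

test_that("social-desirability scoring counts keyed matches", {
  key <- rep_len(c(1L, 0L), 13)
  expect_equal(score_social_desirability(key, key), 13L)
  expect_equal(score_social_desirability(1L - key, key), 0L)
  resp <- key
  resp[c(2, 5, 6, 9, 11, 12)] <- 1L - resp[c(2, 5, 6, 9, 11, 12)]
  expect_equal(score_social_desirability(resp, key), 7L)
  expect_error(score_social_desirability(key[1:12], key), "13")
})

test_that("Cronbach's alpha matches its definitional formula on a fixture", {
  withr::with_seed(31, {
    latent <- rnorm(50)
    items <- sapply(1:5, function(i) latent + rnorm(50, sd = 0.8))
    a <- cronbach_alpha(items)
    k <- 5
    expected <- k / (k - 1) * (1 - sum(apply(items, 2, var)) / var(rowSums(items)))
    expect_equal(a, expected)
    expect_gt(a, 0.5)  # strongly parallel items are internally consistent
  })
  expect_error(cronbach_alpha(matrix(1, 3, 1)), ">= 2 items")
})

test_that("screening applies rules in order with one reason each", {
  battery <- dilemma_battery()
  records <- tibble::tibble(
    participant_id = paste0("p", 1:5),
    acute_stress = c(1L, 0L, 0L, 1L, 0L),
    attention_pass = c(1L, 0L, 1L, 0L, 1L)
  )
  responses <- tidyr::expand_grid(participant_id = paste0("p", 1:5),
                                  item_id = battery$item_id)
  # p3 misses one item (23/24)
  responses <- responses[!(responses$participant_id == "p3" &
                             responses$item_id == battery$item_id[1]), ]
  out <- screen_participants(records, responses)
  expect_equal(out$retained, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # p4 has both acute stress and a failed attention check: first rule wins
  expect_equal(out$reason, c("acute_stress", "attention_fail", "incomplete",
                             "acute_stress", NA))
})

test_that("screening retains everyone when no rule fires", {
  battery <- dilemma_battery()
  records <- tibble::tibble(participant_id = paste0("p", 1:3),
                            acute_stress = 0L, attention_pass = 1L)
  responses <- tidyr::expand_grid(participant_id = records$participant_id,
                                  item_id = battery$item_id)
  out <- screen_participants(records, responses)
  expect_true(all(out$retained))
  expect_true(all(is.na(out$reason)))
})

test_that("median split partitions with the documented tie policy", {
  d <- tibble::tibble(id = 1:4, s = c(1, 2, 3, 4))
  out <- median_split(d, s)
  expect_equal(as.character(out$split_group), c("low", "low", "high", "high"))

  d2 <- tibble::tibble(id = 1:4, s = c(1, 2, 2, 3))
  low_default <- median_split(d2, s)
  expect_equal(as.character(low_default$split_group),
               c("low", "low", "low", "high"))
  high_tie <- median_split(d2, s, tie = "high")
  expect_equal(as.character(high_tie$split_group),
               c("low", "high", "high", "high"))

  expect_error(median_split(tibble::tibble(s = c(2, 2, 2)), s), "degenerate")
})

test_that("median split partition properties hold and summaries have M/SD/N", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      n <- sample(5:40, 1)
      d <- tibble::tibble(s = rnorm(n))
      out <- median_split(d, s)
      expect_equal(sum(out$split_group == "low") + sum(out$split_group == "high"), n)
      # continuous draws: no ties at the median, so groups are separated
      expect_lte(max(out$s[out$split_group == "low"]),
                 min(out$s[out$split_group == "high"]))
    }
  })
  d <- tibble::tibble(s = c(10, 12, 20, 25, 30, 31))
  summ <- attr(median_split(d, s), "summary")
  expect_setequal(names(summ), c("split_group", "n", "mean", "sd"))
  expect_equal(sum(summ$n), 6)
  expect_equal(summ$mean[summ$split_group == "high"], mean(c(25, 30, 31)))
  expect_equal(summ$sd[summ$split_group == "low"], sd(c(10, 12, 20)))
})
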