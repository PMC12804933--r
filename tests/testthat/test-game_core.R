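test_that("one-shot payoffs follow the R/S/T/P convention", {
  pp <- evaluation_payoffs()
  expect_equal(one_shot_payoff("C", "C", pp), 3)
  expect_equal(one_shot_payoff("D", "C", pp), 5)
  expect_equal(one_shot_payoff("C", "D", pp), 0)
  expect_equal(one_shot_payoff("D", "D", pp), 1)
  expect_equal(one_shot_payoff("C", "D", training_payoffs()), 0)
  expect_error(one_shot_payoff("X", "C", pp), "action")
})

test_that("game classification by greediness and unfear signs", {
  expect_equal(classify_game(payoff_params(3, 0, 5, 1)), "PD")
  expect_equal(classify_game(payoff_params(R = 3, S = 2, T = 4, P = 1)), "SG")
  expect_equal(classify_game(payoff_params(R = 3, S = 0, T = 2, P = 1)), "SH")
  expect_equal(classify_game(payoff_params(R = 3, S = 2, T = 2.5, P = 1)), "HG")
  expect_equal(classify_game(payoff_params(R = 3, S = 1, T = 2, P = 1)),
               "boundary")
})

test_that("match configuration validates its inputs", {
  expect_error(match_config(rounds = 0), "rounds")
  expect_error(match_config(noise = 1.5), "noise")
  expect_error(match_config(first_a = "X"), "first-move")
})

test_that("self-play traces reproduce the characteristic recoveries", {
  cfg_cd <- match_config(first_a = "C", first_b = "D")
  cfg_dd <- match_config(first_a = "D", first_b = "D")

  m <- play_match(mtbr_strategy(), mtbr_strategy(), cfg_cd)
  expect_equal(first_mutual_coop(m), 2)
  expect_true(all(m$actions_a[2:20] == "C" & m$actions_b[2:20] == "C"))

  expect_equal(first_mutual_coop(
    play_match(mtbr_strategy(), mtbr_strategy(), cfg_dd)), 3)

  g <- make_mentor("GradualTFT")
  expect_equal(first_mutual_coop(play_match(g, g, cfg_cd)), 4)
  expect_equal(first_mutual_coop(play_match(g, g, cfg_dd)), 3)

  tft <- make_mentor("TFT")
  expect_equal(first_mutual_coop(play_match(tft, tft, cfg_cd)), Inf)
  dd <- play_match(tft, tft, cfg_dd)
  expect_true(all(dd$actions_a == "D" & dd$actions_b == "D"))

  cc <- play_match(tft, tft, match_config(first_a = "C", first_b = "C"))
  expect_equal(cc$mean_a, 3)
  expect_equal(cc$mean_b, 3)
})

test_that("the match engine agrees with an independent table simulator", {
  set.seed(42)
  for (i in 1:25) {
    ta <- sample(0:1, 20, replace = TRUE)
    tb <- sample(0:1, 20, replace = TRUE)
    fa <- sample(0:1, 1); fb <- sample(0:1, 1)
    ref <- ref_table_match(ta, tb, fa, fb, 30)
    m <- play_match(table_strategy(ta), table_strategy(tb),
                    match_config(rounds = 30,
                                 first_a = c("C", "D")[fa + 1],
                                 first_b = c("C", "D")[fb + 1]))
    expect_equal(ifelse(m$actions_a == "D", 1L, 0L), ref$actions_a)
    expect_equal(ifelse(m$actions_b == "D", 1L, 0L), ref$actions_b)
    expect_equal(m$mean_a, ref$mean_a)
    expect_equal(m$mean_b, ref$mean_b)
  }
})

test_that("per-round payoffs are consistent with executed actions", {
  set.seed(1)
  pp <- evaluation_payoffs()
  strats <- list(mtbr_strategy(), make_mentor("GTFT0.3"),
                 make_mentor("WSLS"), zd_strategy("ZDExtort2"))
  for (i in 1:10) {
    pair <- sample(strats, 2)
    m <- play_match(pair[[1]], pair[[2]], match_config(noise = 0.05), pp)
    for (t in seq_len(m$rounds)) {
      expect_equal(m$payoffs_a[t],
                   one_shot_payoff(m$actions_a[t], m$actions_b[t], pp))
      expect_equal(m$payoffs_b[t],
                   one_shot_payoff(m$actions_b[t], m$actions_a[t], pp))
    }
    expect_equal(m$mean_a, mean(m$payoffs_a))
    expect_equal(m$mean_b, mean(m$payoffs_b))
  }
})

test_that("noise-free deterministic matches are bit-reproducible", {
  run <- function() {
    set.seed(99)
    play_match(mtbr_strategy(), make_mentor("GradualTFT"))
  }
  expect_identical(run(), run())
})

test_that("execution noise flips actions at the configured rate", {
  set.seed(2)
  allc <- make_mentor("AllC")
  eta <- 0.05
  m <- play_match(allc, allc, match_config(rounds = 4000, noise = eta,
                                           first_a = "C", first_b = "C"))
  defects <- mean(c(m$actions_a, m$actions_b) == "D")
  se <- sqrt(eta * (1 - eta) / 8000)
  expect_lt(abs(defects - eta), 3 * se)
})

test_that("seat order only swaps the payoff distribution", {
  set.seed(3)
  a <- make_mentor("WSLS"); b <- zd_strategy("ZDGTFT2")
  ab <- expected_match_payoffs(a, b, n_reps = 4000)
  ba <- expected_match_payoffs(b, a, n_reps = 4000)
  expect_lt(abs(ab$mean_a - ba$mean_b), 3 * (ab$se_a + ba$se_b))
  expect_lt(abs(ab$mean_b - ba$mean_a), 3 * (ab$se_b + ba$se_a))
})

test_that("Monte-Carlo means converge to the first-move enumeration", {
  set.seed(4)
  ex <- exact_match_payoffs(mtbr_strategy(), mtbr_strategy())
  expect_equal(ex$mean_a, 2.9375)
  g <- make_mentor("GradualTFT")
  expect_equal(exact_match_payoffs(g, g)$mean_a, 2.9125)
  mc <- expected_match_payoffs(mtbr_strategy(), mtbr_strategy(),
                               n_reps = 8000)
  expect_lt(abs(mc$mean_a - 2.9375), 3 * mc$se_a + 1e-9)
  # mutual defection locks two grudge players that both open with D
  hg <- make_mentor("HoldAGrudge")
  m <- play_match(hg, hg, match_config(first_a = "D", first_b = "D"))
  expect_equal(m$mean_a, 1)
})

test_that("match records serialize to tidy and JSON forms", {
  set.seed(5)
  m <- play_match(make_mentor("TFT"), make_mentor("WSLS"))
  df <- as.data.frame(m)
  expect_equal(nrow(df), 40)
  expect_named(df, c("round", "player", "action", "payoff"))
  js <- jsonlite::fromJSON(match_record_json(m))
  expect_equal(nchar(js$actions_a), 20)
  expect_equal(js$mean_a, m$mean_a)
})
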