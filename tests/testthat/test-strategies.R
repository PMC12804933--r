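test_that("state counts match direct enumeration of partial histories", {
  expect_equal(count_states(2, 1), 4)
  expect_equal(count_states(2, 2), 20)
  expect_equal(count_states(3, 2), 90)  # 3^2 + 3^4
  # enumeration oracle: number of sequences of (opp, own) pairs, length 1..l
  enum <- function(M, l) sum(vapply(seq_len(l), function(k) (M^2)^k, 0))
  for (M in 2:3) for (l in 1:3)
    expect_equal(count_states(M, l), enum(M, l))
  expect_error(count_states(1, 2), "M >= 2")
})

test_that("the codec is a bijection over all partial histories", {
  codec <- state_codec(2, 2)
  pairs1 <- expand.grid(opp = 0:1, own = 0:1)
  hists <- c(
    lapply(seq_len(nrow(pairs1)), function(i) as.matrix(pairs1[i, ])),
    apply(expand.grid(o2 = 0:1, m2 = 0:1, o1 = 0:1, m1 = 0:1), 1,
          function(r) rbind(c(r["o2"], r["m2"]), c(r["o1"], r["m1"])),
          simplify = FALSE)
  )
  hists <- lapply(hists, function(h) {
    colnames(h) <- c("opp", "own"); h
  })
  idx <- vapply(hists, encode_state, 0L, codec = codec)
  expect_equal(sort(idx), 0:19)
  for (i in seq_along(hists)) {
    h <- decode_state(idx[i], codec)
    expect_equal(unname(h), unname(matrix(hists[[i]], ncol = 2)))
  }
  expect_false(encode_state(rbind(c(1, 0)), codec) ==
                 encode_state(rbind(c(0, 1)), codec))
  expect_error(encode_state(rbind(c(0, 0), c(0, 0), c(0, 0)), codec),
               "exceeds memory")
})

test_that("mentor automata implement their documented rules", {
  cfg <- function(fa, fb, L = 20) match_config(L, first_a = fa, first_b = fb)
  acts <- function(m) paste(m$actions_a, collapse = "")

  # TFT mirrors; GTFT forgives about 30% of defections
  tft <- make_mentor("TFT")
  m <- play_match(tft, make_mentor("AllD"), cfg("C", "D", 6))
  expect_equal(acts(m), "CDDDDD")
  set.seed(10)
  g <- play_match(make_mentor("GTFT0.3"), make_mentor("AllD"),
                  cfg("C", "D", 6000))
  forgive <- mean(g$actions_a[-1] == "C")
  expect_lt(abs(forgive - 0.3), 3 * sqrt(0.3 * 0.7 / 6000))

  # WSLS repeats after R/T, switches after S/P
  w <- play_match(make_mentor("WSLS"), make_mentor("AllD"), cfg("C", "D", 6))
  expect_equal(acts(w), "CDCDCD")
  w2 <- play_match(make_mentor("WSLS"), make_mentor("AllC"), cfg("D", "C", 6))
  expect_equal(acts(w2), "DDDDDD")  # temptation is a success

  # Hold-a-Grudge defects forever after one defection
  hg <- play_match(make_mentor("HoldAGrudge"),
                   reactive1_strategy(c(1, 1, 1, 1), first_move = "D"),
                   cfg("C", "D", 6))
  expect_equal(acts(hg), "CDDDDD")

  # Fool-Me-Once: one warning defection, forgiveness, then permanence
  fmo <- play_match(make_mentor("FoolMeOnce"),
                    reactive1_strategy(c(1, 1, 1, 1), first_move = "D"),
                    cfg("C", "D", 6))
  expect_equal(acts(fmo), "CDCCCC")
  fmo2 <- play_match(make_mentor("FoolMeOnce"), make_mentor("TFT"),
                     cfg("C", "D", 8))
  # warning at round 2 is echoed by TFT at round 3 (second defection)
  expect_equal(acts(fmo2), "CDCDDDDD")

  # grudge state does not leak across matches
  hg2 <- make_mentor("HoldAGrudge")
  play_match(hg2, make_mentor("AllD"), cfg("C", "D"))
  clean <- play_match(hg2, make_mentor("AllC"), cfg("C", "C", 6))
  expect_equal(acts(clean), "CCCCCC")
})

test_that("OmegaTFT breaks deadlocks and punishes erratic opponents", {
  om <- make_mentor("OmegaTFT")
  # self-play from opposite first moves: alternation until the deadlock
  # counter trips, then sustained mutual cooperation
  m <- play_match(om, om, match_config(first_a = "C", first_b = "D"))
  r <- first_mutual_coop(m)
  expect_true(is.finite(r))
  expect_true(all(m$actions_a[r:20] == "C" & m$actions_b[r:20] == "C"))
  # an unconditional alternator eventually trips the randomness counter
  alternator <- reactive1_strategy(c(0, 0, 1, 1), first_move = "C",
                                   name = "alternator")
  m2 <- play_match(om, alternator, match_config(rounds = 40,
                                                first_a = "C",
                                                first_b = "C"))
  expect_true(all(m2$actions_a[25:40] == "D"))
})

test_that("zero-determinant presets match the closed-form derivation", {
  expect_equal(unname(zd_probabilities(1, 0.5, 1 / 9, eval_pp)),
               c(8 / 9, 1 / 2, 1 / 3, 0))
  expect_equal(unname(zd_probabilities(3, 0.5, 0.25, eval_pp)),
               c(1, 1 / 8, 1, 1 / 4))
  expect_equal(unname(zd_strategy("ZDExtort4")$p),
               c(11 / 17, 0, 8 / 17, 0))
  expect_error(zd_probabilities(3, 0.5, 2, eval_pp), "infeasible")
})

test_that("stationary payoffs solve the joint-action Markov chain", {
  expect_equal(stationary_payoffs(rep(1, 4), rep(1, 4)), c(3, 3),
               tolerance = 1e-6)
  expect_equal(stationary_payoffs(rep(0, 4), rep(1, 4)), c(5, 0),
               tolerance = 1e-6)
})

test_that("every ZD preset enforces its linear payoff relation", {
  set.seed(11)
  for (nm in names(mtbr:::ZD_PRESETS)) {
    zd <- zd_strategy(nm)
    for (r in 1:100) {
      q <- runif(4)
      pp <- stationary_payoffs(zd$p, q)
      expect_lt(abs(pp[2] - zd$l - zd$s * (pp[1] - zd$l)), 1e-8)
    }
  }
  # slope-zero presets pin the opponent's payoff at the baseline
  mis <- zd_strategy("ZDMischief")
  expect_equal(stationary_payoffs(mis$p, runif(4))[2], 1, tolerance = 1e-8)
})

test_that("the MTBR table implements its three decision rules", {
  s <- mtbr_strategy()
  codec <- state_codec(2, 2)
  at <- function(h) s$table[encode_state(h, codec) + 1]
  expect_equal(at(rbind(c(opp = 1, own = 0))), 0)              # rule i
  expect_equal(at(rbind(c(1, 1), c(1, 1))), 0)                 # rule ii
  expect_equal(at(rbind(c(0, 0), c(1, 0))), 1)                 # rule iii
  # rule iii everywhere else: action equals opponent's last move
  for (idx in 0:19) {
    h <- decode_state(idx, codec)
    k <- nrow(h)
    expected <- if (k == 1 && h[1, "opp"] == 1 && h[1, "own"] == 0) 0L
                else if (k == 2 && all(h == 1)) 0L
                else h[k, "opp"]
    expect_equal(s$table[idx + 1], unname(expected))
  }
})

test_that("MTBR out-earns GradualTFT in self-play", {
  expect_equal(exact_match_payoffs(mtbr_strategy(), mtbr_strategy())$mean_a,
               2.9375)
  g <- make_mentor("GradualTFT")
  expect_equal(exact_match_payoffs(g, g)$mean_a, 2.9125)
  expect_gt(2.9375, 2.9125)
  expect_equal(exact_match_payoffs(make_mentor("TFT"),
                                   make_mentor("TFT"))$mean_a, 2.25)
})

test_that("no deterministic short-memory opponent beats R against MTBR", {
  long <- function(opp, fm)
    play_match(opp, mtbr_strategy(),
               match_config(rounds = 999, first_a = fm, first_b = "C"))$mean_a
  for (opp in deterministic_memory_one())
    expect_lte(long(opp, opp$first_move), 3 + 0.01)
  set.seed(12)
  for (i in 1:10000) {
    fm <- sample(c("C", "D"), 1)
    opp <- table_strategy(sample(0:1, 20, replace = TRUE), first_move = fm)
    expect_lte(long(opp, fm), 3 + 0.01)
  }
})

test_that("rosters resolve and serialize", {
  s1 <- roster_set1()
  expect_length(s1, 7)
  s2 <- roster_set2()
  expect_length(s2, 15)
  expect_length(make_roster("set2+MTBR"), 16)
  expect_error(make_roster(c("TFT", "NotAStrategy")), "unknown")
  js <- jsonlite::fromJSON(roster_json(make_roster(c("MTBR", "TFT"))),
                           simplifyVector = FALSE)
  expect_equal(nchar(js$MTBR$table), 20)
})
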