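two_roster <- function() make_roster(c("TFT", "WSLS"))

test_that("the Fermi rule has its fixed points and complementarity", {
  expect_equal(imitation_probability(2, 2, 5), 0.5)
  expect_equal(imitation_probability(0.3, 2.7, 0), 0.5)
  expect_equal(imitation_probability(1, 3, 3), 1 / (1 + exp(-6)))
  set.seed(40)
  for (i in 1:50) {
    a <- runif(1, 0, 5); b <- runif(1, 0, 5); d <- runif(1, 0, 10)
    expect_equal(imitation_probability(a, b, d) +
                   imitation_probability(b, a, d), 1)
  }
})

test_that("population structures have the right geometry", {
  set.seed(41)
  cfg <- evolution_config(two_roster(), n = 100)
  pop <- build_population(cfg)
  expect_null(pop$graph)   # complete graph kept implicit
  expect_equal(sum(pop$counts), 100)

  lat <- build_population(evolution_config(two_roster(), n = 100,
                                           network = "lattice"))
  deg <- igraph::degree(lat$graph)
  expect_equal(as.vector(table(deg)), c(4L, 32L, 64L))  # corners, edges, bulk
  expect_error(evolution_config(two_roster(), n = 90, network = "lattice"),
               "square")

  ba <- build_population(evolution_config(two_roster(), n = 5000,
                                          network = "ba"))
  expect_lt(abs(mean(igraph::degree(ba$graph)) - 4) / 4, 0.01)
})

test_that("full mutation drives frequencies to the uniform mixture", {
  set.seed(42)
  A <- matrix(c(3, 0, 5, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("TFT", "WSLS"), c("TFT", "WSLS")))
  cfg <- evolution_config(two_roster(), n = 100, delta = 3, mu = 1,
                          steps = 2e5, burn_in = 1e4, payoff_matrix = A)
  res <- run_evolution(cfg)
  expect_lt(max(abs(res$avg_freq - 0.5)), 0.02)
})

test_that("a homogeneous population without mutation is absorbing", {
  set.seed(43)
  A <- matrix(1, 2, 2, dimnames = list(c("TFT", "WSLS"), c("TFT", "WSLS")))
  cfg <- evolution_config(two_roster(), n = 50, delta = 1, mu = 0,
                          steps = 1e4, payoff_matrix = A,
                          initial_counts = c(50L, 0L))
  res <- run_evolution(cfg)
  expect_equal(unname(res$final_counts), c(50, 0))
  expect_lt(res$events, 1e4)  # early stop at absorption
})

test_that("neutral drift fixes a strategy at its initial frequency", {
  set.seed(44)
  A <- matrix(1, 2, 2, dimnames = list(c("TFT", "WSLS"), c("TFT", "WSLS")))
  fix <- replicate(2000, {
    cfg <- evolution_config(two_roster(), n = 50, delta = 0, mu = 0,
                            steps = 1e6, payoff_matrix = A,
                            initial_counts = c(15L, 35L),
                            record_stride = 1e6)
    run_evolution(cfg)$final_counts[1] == 50
  })
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_lt(abs(mean(fix) - 0.3), 3 * se)
})

test_that("recorded frequencies always sum to one", {
  set.seed(45)
  roster <- make_roster(c("TFT", "WSLS", "MTBR"))
  A <- estimate_payoff_matrix(roster, n_reps = 200)
  cfg <- evolution_config(roster, n = 60, delta = 2, mu = 0.05,
                          steps = 2e4, payoff_matrix = A,
                          record_stride = 500)
  tr <- run_evolution(cfg)$trajectory
  sums <- tapply(tr$frequency, tr$epoch, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("a majority of cooperators ousts an AllD-like grudge holder", {
  set.seed(46)
  ros <- list(MTBR = mtbr_strategy(), HoldAGrudge = make_mentor("HoldAGrudge"))
  A <- estimate_payoff_matrix(ros, n_reps = 2000)
  wins <- replicate(100, {
    cfg <- evolution_config(ros, n = 200, delta = 3, mu = 0, steps = 1e6,
                            payoff_matrix = A,
                            initial_counts = c(180L, 20L),
                            record_stride = 1e6)
    run_evolution(cfg)$final_counts[["MTBR"]] == 200
  })
  expect_gte(mean(wins), 0.95)
})

test_that("MTBR is the usual winner of the noise-free set-2 contest", {
  set.seed(47)
  roster <- make_roster("set2+MTBR")
  A <- estimate_payoff_matrix(roster, n_reps = 2000)
  modal <- replicate(50, {
    cfg <- evolution_config(roster, n = 500, delta = 3, mu = 0,
                            steps = 3e6, payoff_matrix = A,
                            record_stride = 3e6)
    names(which.max(run_evolution(cfg)$final_counts))
  })
  expect_gt(mean(modal == "MTBR"), 0.5)
})

test_that("sampled-payoff dynamics run on a lattice", {
  set.seed(48)
  roster <- make_roster(c("TFT", "HoldAGrudge"))
  cfg <- evolution_config(roster, n = 25, delta = 2, mu = 0.02,
                          network = "lattice", steps = 400,
                          record_stride = 100)
  res <- run_evolution(cfg)
  expect_equal(sum(res$final_counts), 25)
  sums <- tapply(res$trajectory$frequency, res$trajectory$epoch, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("game sweep labels cells and tracks MTBR prevalence", {
  set.seed(49)
  base <- evolution_config(make_roster(c("TFT", "GTFT0.3", "MTBR")),
                           n = 100, delta = 1, mu = 0, steps = 2e5,
                           n_reps_matrix = 300, record_stride = 2e5)
  grid <- sweep_games(base, t_values = c(5, 2.5), s_values = c(0), reps = 2)
  expect_equal(nrow(grid), 2)
  expect_equal(grid$game_type, c("PD", "SH"))
  expect_true(all(grid$mtbr_fraction >= 0 & grid$mtbr_fraction <= 1))
  pd <- grid[grid$game_type == "PD", ]
  expect_gt(pd$mtbr_fraction, 0.5)
})
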