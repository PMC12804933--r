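# Payoff structures, game classification and the repeated-match engine.

#' Payoff parameters of a symmetric two-player, two-action game
#'
#' Bundles the four payoffs of a symmetric matrix game: mutual cooperation
#' pays `R` to each player, mutual defection pays `P`, and unilateral
#' cooperation pays the cooperator the sucker's payoff `S` while the
#' defector collects the temptation payoff `T`.
#'
#' Two parameter sets recur throughout the package: the classical
#' evaluation Prisoner's Dilemma `R = 3, S = 0, T = 5, P = 1`
#' ([evaluation_payoffs()]) and the training set `R = 2, S = 0, T = 3,
#' P = 0.1` whose mild punishment favours the emergence of cooperative
#' policies during Q-learning ([training_payoffs()]).
#'
#' @param R reward for mutual cooperation.
#' @param S sucker's payoff (cooperate against a defector).
#' @param T temptation payoff (defect against a cooperator).
#' @param P punishment for mutual defection.
#' @return An object of class `payoff_params`.
#' @examples
#' pp <- payoff_params(R = 3, S = 0, T = 5, P = 1)
#' classify_game(pp)
#' @export
payoff_params <- function(R = 3, S = 0, T = 5, P = 1) {
  vals <- c(R = R, S = S, T = T, P = P)
  if (!all(is.finite(vals))) stop("payoffs must be finite numbers")
  structure(as.list(vals), class = "payoff_params")
}

#' @rdname payoff_params
#' @export
evaluation_payoffs <- function() payoff_params(R = 3, S = 0, T = 5, P = 1)

#' @rdname payoff_params
#' @export
training_payoffs <- function() payoff_params(R = 2, S = 0, T = 3, P = 0.1)

#' @export
print.payoff_params <- function(x, ...) {
  cat(sprintf("payoffs: R=%g S=%g T=%g P=%g (%s)\n",
              x$R, x$S, x$T, x$P, classify_game(x)))
  invisible(x)
}

payoff_vector <- function(payoffs) {
  stopifnot(inherits(payoffs, "payoff_params"))
  c(payoffs$R, payoffs$S, payoffs$T, payoffs$P)
}

#' One-shot payoff of an action pair
#'
#' @param a_self,a_opp actions, `"C"` or `"D"`.
#' @param payoffs a [payoff_params()] object.
#' @return The focal player's payoff: `R` for (C,C), `S` for (C,D), `T` for
#'   (D,C) and `P` for (D,D).
#' @examples
#' one_shot_payoff("D", "C", evaluation_payoffs())  # temptation, 5
#' @export
one_shot_payoff <- function(a_self, a_opp, payoffs) {
  s <- action_code(a_self)
  o <- action_code(a_opp)
  pv <- payoff_vector(payoffs)
  pv[2L * s + o + 1L]
}

action_code <- function(a) {
  if (is.numeric(a)) {
    if (!all(a %in% c(0, 1))) stop("numeric actions must be 0 (C) or 1 (D)")
    return(as.integer(a))
  }
  code <- c(C = 0L, D = 1L)[as.character(a)]
  if (anyNA(code)) stop("unknown action symbol; use \"C\" or \"D\"")
  unname(code)
}

action_label <- function(code) c("C", "D")[code + 1L]

#' Classify a game by greediness and unfear
#'
#' The signs of the greediness `T - R` and unfear `S - P` partition
#' symmetric two-action games into the Prisoner's Dilemma (`PD`:
#' greedy, fearful), Snowdrift (`SG`: greedy, unfearful), Stag-hunt
#' (`SH`) and Harmony (`HG`) games. Games on a boundary (either
#' difference exactly zero) are labelled `"boundary"`.
#'
#' @param payoffs a [payoff_params()] object.
#' @return One of `"PD"`, `"SG"`, `"SH"`, `"HG"`, `"boundary"`.
#' @export
classify_game <- function(payoffs) {
  greed <- payoffs$T - payoffs$R
  unfear <- payoffs$S - payoffs$P
  if (greed == 0 || unfear == 0) return("boundary")
  if (greed > 0) {
    if (unfear < 0) "PD" else "SG"
  } else {
    if (unfear < 0) "SH" else "HG"
  }
}

#' Configuration of a repeated match
#'
#' @param rounds number of rounds `L` (default 20).
#' @param noise execution-error probability `eta` in `[0, 1]`: each
#'   player's intended action is independently flipped with this
#'   probability before execution; both players observe (and react to)
#'   executed actions only, and payoffs are computed from executed actions.
#' @param first_a,first_b first-move rule for each seat: `"strategy"`
#'   (use the strategy's own rule, which defaults to a fair coin),
#'   `"random"`, `"C"` or `"D"`.
#' @return An object of class `match_config`.
#' @export
match_config <- function(rounds = 20L, noise = 0,
                         first_a = "strategy", first_b = "strategy") {
  if (rounds < 1) stop("rounds must be >= 1")
  if (noise < 0 || noise > 1) stop("noise must lie in [0, 1]")
  structure(list(rounds = as.integer(rounds), noise = noise,
                 first_a = first_code(first_a), first_b = first_code(first_b)),
            class = "match_config")
}

first_code <- function(rule) {
  code <- c(C = 0L, D = 1L, random = 2L, strategy = 3L)[rule]
  if (anyNA(code)) stop("first-move rule must be C, D, random or strategy")
  unname(code)
}

#' Play one repeated match between two strategies
#'
#' Both strategies are reset to their initial internal state, round-1
#' actions are drawn by the first-move rules, and each later round's
#' intended actions are produced from the executed history. With
#' probability `noise` each intended action is independently flipped
#' before execution.
#'
#' Randomness (first moves, stochastic strategies, noise) comes from R's
#' RNG, so `set.seed()` makes matches reproducible.
#'
#' @param strat_a,strat_b strategies (see [make_mentor()],
#'   [mtbr_strategy()], [zd_strategy()], [table_strategy()]).
#' @param config a [match_config()].
#' @param payoffs a [payoff_params()].
#' @return A `match_record`: executed action sequences, per-round payoffs,
#'   and per-player means (the arithmetic mean over rounds).
#' @examples
#' set.seed(1)
#' m <- play_match(mtbr_strategy(), mtbr_strategy(),
#'                 match_config(first_a = "C", first_b = "D"),
#'                 evaluation_payoffs())
#' m$mean_a
#' @export
play_match <- function(strat_a, strat_b, config = match_config(),
                       payoffs = evaluation_payoffs()) {
  res <- cpp_play_match(strategy_spec(strat_a), strategy_spec(strat_b),
                        config$rounds, config$noise, payoff_vector(payoffs),
                        config$first_a, config$first_b)
  structure(list(
    actions_a = action_label(res$actions_a),
    actions_b = action_label(res$actions_b),
    payoffs_a = res$payoffs_a, payoffs_b = res$payoffs_b,
    mean_a = res$mean_a, mean_b = res$mean_b,
    rounds = config$rounds, noise = config$noise
  ), class = "match_record")
}

#' @export
print.match_record <- function(x, ...) {
  cat(sprintf("match of %d rounds (noise %g)\n", x$rounds, x$noise))
  cat(" A:", paste(x$actions_a, collapse = ""),
      sprintf(" mean %.4f\n", x$mean_a))
  cat(" B:", paste(x$actions_b, collapse = ""),
      sprintf(" mean %.4f\n", x$mean_b))
  invisible(x)
}

#' Tidy per-round view of a match
#'
#' @param x a `match_record`.
#' @param ... unused.
#' @return A data frame with columns `round`, `player`, `action`, `payoff`.
#' @export
as.data.frame.match_record <- function(x, ...) {
  L <- x$rounds
  data.frame(
    round = rep(seq_len(L), 2L),
    player = rep(c("A", "B"), each = L),
    action = c(x$actions_a, x$actions_b),
    payoff = c(x$payoffs_a, x$payoffs_b),
    stringsAsFactors = FALSE
  )
}

#' Serialize a match record to JSON
#'
#' Actions are written as strings like `"CDCC..."` together with the
#' per-round payoff arrays and means.
#'
#' @param x a `match_record`.
#' @return A JSON string.
#' @export
match_record_json <- function(x) {
  jsonlite::toJSON(list(
    rounds = x$rounds, noise = x$noise,
    actions_a = paste(x$actions_a, collapse = ""),
    actions_b = paste(x$actions_b, collapse = ""),
    payoffs_a = x$payoffs_a, payoffs_b = x$payoffs_b,
    mean_a = x$mean_a, mean_b = x$mean_b
  ), auto_unbox = TRUE, digits = NA)
}

#' Monte-Carlo mean match payoffs of a strategy pair
#'
#' Plays `n_reps` independent matches (first moves and any strategy
#' stochasticity resampled each repeat) and reports per-seat mean payoffs
#' with standard errors.
#'
#' @inheritParams play_match
#' @param n_reps number of independent matches.
#' @return A list with `mean_a`, `mean_b`, `se_a`, `se_b`.
#' @export
expected_match_payoffs <- function(strat_a, strat_b, config = match_config(),
                                   payoffs = evaluation_payoffs(),
                                   n_reps = 10000L) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  cpp_match_means(strategy_spec(strat_a), strategy_spec(strat_b),
                  config$rounds, config$noise, payoff_vector(payoffs),
                  as.integer(n_reps), config$first_a, config$first_b)
}

#' Exact mean payoffs of a deterministic pair by first-move enumeration
#'
#' For two deterministic strategies in a noise-free match the only
#' randomness is the pair of first moves; the expectation over random
#' first moves is the equal-weight average over the (at most four)
#' first-move profiles. Falls back with an error if either strategy is
#' stochastic or noise is nonzero.
#'
#' @inheritParams play_match
#' @return A list with `mean_a`, `mean_b` (exact expectations) and
#'   `se_a = se_b = 0`.
#' @examples
#' exact_match_payoffs(mtbr_strategy(), mtbr_strategy())$mean_a  # 2.9375
#' @export
exact_match_payoffs <- function(strat_a, strat_b, config = match_config(),
                                payoffs = evaluation_payoffs()) {
  if (config$noise != 0) stop("exact enumeration requires noise = 0")
  if (!is_deterministic(strat_a) || !is_deterministic(strat_b))
    stop("exact enumeration requires deterministic strategies")
  firsts_for <- function(cfg_first, strat) {
    if (cfg_first %in% c(0L, 1L)) return(cfg_first)
    fm <- first_code(strat$first_move)
    if (fm %in% c(0L, 1L)) fm else c(0L, 1L)
  }
  fa <- firsts_for(config$first_a, strat_a)
  fb <- firsts_for(config$first_b, strat_b)
  ma <- mb <- 0
  for (f1 in fa) for (f2 in fb) {
    r <- cpp_play_match(strategy_spec(strat_a), strategy_spec(strat_b),
                        config$rounds, 0, payoff_vector(payoffs), f1, f2)
    ma <- ma + r$mean_a
    mb <- mb + r$mean_b
  }
  k <- length(fa) * length(fb)
  list(mean_a = ma / k, mean_b = mb / k, se_a = 0, se_b = 0)
}
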