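# History-state encoding and the playable strategy zoo: mentor automata,
# zero-determinant (memory-one) strategies, the MTBR lookup table, and
# generic table / reactive-1 strategies.

KIND_CODES <- c(table = 0L, reactive1 = 1L, tft = 2L, gtft = 3L, wsls = 4L,
                grudge = 5L, foolmeonce = 6L, omegatft = 7L, gradualtft = 8L,
                allc = 9L, alld = 10L)

#' History-state codec for memory-`l` strategies
#'
#' A player with memory `l` conditions on the last `min(t - 1, l)` rounds
#' of both players' executed actions. Each remembered round contributes
#' one (opponent action, own action) pair; with `M` actions there are
#' `M^2` possible pairs, and histories shorter than `l` (the opening
#' rounds) are distinct states of their own. The codec maps every partial
#' history of length 1..`l`, ordered oldest pair first, to a unique index
#' in `0 .. n_states - 1`.
#'
#' Canonical ordering (used for table strategies and Q-tables): histories
#' of length `k` occupy a contiguous block after all shorter histories;
#' within a block a history is read as a base-`M^2` number, oldest pair
#' first, with pair digit `M * opponent + own` (actions coded C = 0,
#' D = 1). For `M = 2, l = 2` this yields 20 states: indices 0-3 are the
#' one-round histories (opp,own) = (C,C), (C,D), (D,C), (D,D) and indices
#' 4-19 the two-round histories.
#'
#' @param M number of actions (2 throughout the repeated Prisoner's
#'   Dilemma experiments).
#' @param memory memory length `l`.
#' @return An object of class `state_codec` with fields `M`, `memory`,
#'   `n_states`.
#' @export
state_codec <- function(M = 2L, memory = 2L) {
  structure(list(M = as.integer(M), memory = as.integer(memory),
                 n_states = count_states(M, memory)),
            class = "state_codec")
}

#' Number of history states for memory-`l`, `M`-action strategies
#'
#' Counts all partial histories of length 1..`l`:
#' `sum_k M^(2k) = (M^(2l+2) - 1) / (M^2 - 1) - 1`.
#'
#' @inheritParams state_codec
#' @return Integer state count (20 for `M = 2, l = 2`).
#' @export
count_states <- function(M, memory) {
  if (M < 2 || memory < 1) stop("need M >= 2 and memory >= 1")
  sum(as.numeric(M)^(2L * seq_len(memory)))
}

#' Encode a partial history as a state index
#'
#' @param history a matrix or data frame with columns `opp` and `own`
#'   (actions `"C"`/`"D"` or 0/1), one row per remembered round, oldest
#'   first; or a list of `c(opp, own)` pairs.
#' @param codec a [state_codec()].
#' @return Zero-based state index.
#' @export
encode_state <- function(history, codec = state_codec()) {
  h <- normalize_history(history)
  k <- nrow(h)
  if (k < 1) stop("history must contain at least one round")
  if (k > codec$memory)
    stop(sprintf("history of length %d exceeds memory %d", k, codec$memory))
  M <- codec$M
  offset <- if (k > 1) sum(as.numeric(M)^(2L * seq_len(k - 1L))) else 0
  digits <- M * h[, "opp"] + h[, "own"]
  rel <- 0
  for (d in digits) rel <- rel * M^2 + d
  as.integer(offset + rel)
}

#' Decode a state index back into a partial history
#'
#' Inverse of [encode_state()].
#'
#' @param index zero-based state index.
#' @param codec a [state_codec()].
#' @return A matrix with columns `opp`, `own` (0 = C, 1 = D), oldest row
#'   first.
#' @export
decode_state <- function(index, codec = state_codec()) {
  if (index < 0 || index >= codec$n_states) stop("state index out of range")
  M <- codec$M
  k <- 1L
  offset <- 0
  while (index >= offset + M^(2 * k)) {
    offset <- offset + M^(2 * k)
    k <- k + 1L
  }
  rel <- index - offset
  digits <- integer(k)
  for (i in k:1) {
    digits[i] <- rel %% (M^2)
    rel <- rel %/% (M^2)
  }
  cbind(opp = digits %/% M, own = digits %% M)
}

normalize_history <- function(history) {
  if (is.list(history) && !is.data.frame(history))
    history <- do.call(rbind, history)
  if (is.data.frame(history)) history <- as.matrix(history)
  if (is.null(dim(history))) history <- matrix(history, nrow = 1)
  if (is.null(colnames(history))) colnames(history) <- c("opp", "own")
  h <- cbind(opp = action_code(history[, "opp"]),
             own = action_code(history[, "own"]))
  h
}

new_strategy <- function(name, kind, first_move = "random", ...) {
  structure(c(list(name = name, kind = kind, first_move = first_move),
              list(...)),
            class = "ipd_strategy")
}

#' @export
print.ipd_strategy <- function(x, ...) {
  cat(sprintf("strategy %s (%s, first move %s)\n",
              x$name, x$kind, x$first_move))
  invisible(x)
}

# Internal: the list handed to the C++ engine.
strategy_spec <- function(strategy) {
  stopifnot(inherits(strategy, "ipd_strategy"))
  spec <- list(kind_code = KIND_CODES[[strategy$kind]],
               first_code = first_code(strategy$first_move))
  if (strategy$kind == "table") {
    spec$table <- as.integer(strategy$table)
    spec$memory <- as.integer(strategy$memory)
  }
  if (strategy$kind == "reactive1") spec$p <- as.numeric(strategy$p)
  if (strategy$kind == "gtft") spec$g <- strategy$g
  if (strategy$kind == "omegatft") {
    spec$deadlock_threshold <- strategy$deadlock_threshold
    spec$randomness_threshold <- strategy$randomness_threshold
  }
  spec
}

#' Is a strategy's play deterministic given the first moves?
#'
#' @param strategy an `ipd_strategy`.
#' @return `TRUE` when, conditional on the round-1 actions, all later
#'   actions are deterministic functions of the executed history.
#' @export
is_deterministic <- function(strategy) {
  switch(strategy$kind,
         gtft = FALSE,
         reactive1 = all(strategy$p %in% c(0, 1)),
         TRUE)
}

#' Benchmark mentor strategies
#'
#' Constructs one of the seven benchmark ("mentor") strategies used as
#' fixed opponents during Q-learning and in the evaluation rosters. All
#' mentors open with a fair-coin first move and thereafter react to
#' executed actions:
#'
#' * `TFT` replicates the opponent's previous move.
#' * `GTFT0.3` is tit-for-tat that forgives a defection with probability
#'   `g` (default 0.3).
#' * `WSLS` (win-stay-lose-shift) repeats its previous action after a
#'   successful round (own payoff `R` or `T`) and switches otherwise.
#' * `HoldAGrudge` cooperates until the first observed opponent
#'   defection, then defects forever.
#' * `FoolMeOnce` answers the first opponent defection with a single
#'   warning defection and then resumes cooperating; from the second
#'   defection on it defects forever.
#' * `OmegaTFT` is tit-for-tat with deadlock and randomness detection
#'   (thresholds 3 and 8): after observing more than three consecutive
#'   cooperate/defect alternations it cooperates once to break the
#'   deadlock and resets the count; a randomness counter gains one
#'   whenever the opponent's move differs from its own previous move or
#'   from OmegaTFT's move, loses one (floored at zero) when the opponent
#'   repeats itself, and at 8 the strategy defects forever. Counters are
#'   updated after each observed round; the thresholds are checked in the
#'   order randomness, deadlock, then tit-for-tat.
#' * `GradualTFT` keeps a running count `N_D` of opponent defections; a
#'   defection observed while in the normal state triggers `N_D`
#'   punishing defections followed by exactly two cooling-off
#'   cooperations. Defections observed while punishing or cooling raise
#'   `N_D` but do not start a new phase.
#'
#' `AllC` and `AllD` are also available as degenerate baselines.
#'
#' @param name one of `"TFT"`, `"GTFT0.3"`, `"WSLS"`, `"HoldAGrudge"`,
#'   `"FoolMeOnce"`, `"OmegaTFT"`, `"GradualTFT"`, `"AllC"`, `"AllD"`.
#' @param payoffs a [payoff_params()]; used by WSLS to define success.
#' @param g forgiveness probability for `GTFT`.
#' @return An `ipd_strategy`.
#' @export
make_mentor <- function(name, payoffs = evaluation_payoffs(), g = 0.3) {
  switch(name,
    "TFT" = new_strategy("TFT", "tft"),
    "GTFT0.3" = ,
    "GTFT" = new_strategy(sprintf("GTFT%.3g", g), "gtft", g = g),
    "WSLS" = new_strategy("WSLS", "wsls"),
    "HoldAGrudge" = new_strategy("HoldAGrudge", "grudge"),
    "FoolMeOnce" = new_strategy("FoolMeOnce", "foolmeonce"),
    "OmegaTFT" = new_strategy("OmegaTFT", "omegatft",
                              deadlock_threshold = 3L,
                              randomness_threshold = 8L),
    "GradualTFT" = new_strategy("GradualTFT", "gradualtft"),
    "AllC" = new_strategy("AllC", "allc", first_move = "C"),
    "AllD" = new_strategy("AllD", "alld", first_move = "D"),
    stop(sprintf("unknown mentor name \"%s\"", name))
  )
}

MENTOR_NAMES <- c("GradualTFT", "OmegaTFT", "TFT", "GTFT0.3", "FoolMeOnce",
                  "WSLS", "HoldAGrudge")

ZD_PRESETS <- list(
  ZDExtort2   = list(l = quote(P), s = 0.5,  phi = 1 / 9),
  ZDExtort2v2 = list(l = quote(P), s = 0.5,  phi = 1 / 8),
  ZDExtort3   = list(l = quote(P), s = 1 / 3, phi = 3 / 26),
  ZDExtort4   = list(l = quote(P), s = 0.25, phi = 4 / 17),
  ZDGen2      = list(l = quote(R), s = 0.5,  phi = 1 / 8),
  ZDGTFT2     = list(l = quote(R), s = 0.5,  phi = 0.25),
  ZDMischief  = list(l = quote(P), s = 0,    phi = 0.1),
  ZDSet2      = list(l = quote((R + P) / 2), s = 0, phi = 0.25)
)

#' Memory-one cooperation probabilities of a zero-determinant strategy
#'
#' A zero-determinant (ZD) strategy unilaterally enforces the linear
#' relation `pi_opponent = l + s * (pi_self - l)` between the two
#' players' long-run payoffs. Given the baseline payoff `l`, slope `s`
#' and scale `phi`, the enforcing memory-one strategy has cooperation
#' probabilities (indexed by the focal player's own and the opponent's
#' last executed actions)
#' \deqn{p_{CC} = 1 - \phi(1-s)(R-l),\quad
#'       p_{CD} = 1 - \phi[(T-l) + s(l-S)],}
#' \deqn{p_{DC} = \phi[s(T-l) + (l-S)],\quad
#'       p_{DD} = \phi(1-s)(l-P).}
#'
#' @param l baseline payoff.
#' @param s slope of the enforced relation.
#' @param phi scale parameter.
#' @param payoffs a [payoff_params()].
#' @return Named numeric vector `c(p_CC, p_CD, p_DC, p_DD)`.
#' @examples
#' zd_probabilities(l = 1, s = 0.5, phi = 1/9, evaluation_payoffs())
#' @export
zd_probabilities <- function(l, s, phi, payoffs = evaluation_payoffs()) {
  R <- payoffs$R; S <- payoffs$S; T <- payoffs$T; P <- payoffs$P
  p <- c(
    p_CC = 1 - phi * (1 - s) * (R - l),
    p_CD = 1 - phi * ((T - l) + s * (l - S)),
    p_DC = phi * (s * (T - l) + (l - S)),
    p_DD = phi * (1 - s) * (l - P)
  )
  bad <- which(p < -1e-12 | p > 1 + 1e-12)
  if (length(bad))
    stop(sprintf("infeasible ZD parameters: %s outside [0, 1] (%s)",
                 names(p)[bad[1]], format(p[bad[1]])))
  pmin(pmax(p, 0), 1)
}

#' Named zero-determinant strategies
#'
#' Builds one of the eight preset ZD strategies (`ZDExtort2`,
#' `ZDExtort2v2`, `ZDExtort3`, `ZDExtort4`, `ZDGen2`, `ZDGTFT2`,
#' `ZDMischief`, `ZDSet2`) for the given payoffs, or an arbitrary ZD
#' strategy from explicit `(l, s, phi)`. The extortionate presets anchor
#' at `l = P`, the generous ones at `l = R`; `ZDMischief` and `ZDSet2`
#' have slope zero and pin the opponent's payoff at `l` regardless of the
#' opponent's play.
#'
#' @param name preset name, or `NULL` when `l`, `s`, `phi` are given.
#' @param payoffs a [payoff_params()].
#' @param l,s,phi explicit ZD parameters (ignored when `name` is given).
#' @param first_move first-move rule.
#' @return A `reactive1` `ipd_strategy` with fields `p`, `l`, `s`, `phi`.
#' @export
zd_strategy <- function(name = NULL, payoffs = evaluation_payoffs(),
                        l = NULL, s = NULL, phi = NULL,
                        first_move = "random") {
  if (!is.null(name)) {
    preset <- ZD_PRESETS[[name]]
    if (is.null(preset)) stop(sprintf("unknown ZD strategy \"%s\"", name))
    env <- list2env(payoffs[c("R", "S", "T", "P")])
    l <- eval(preset$l, env); s <- preset$s; phi <- preset$phi
  } else {
    name <- sprintf("ZD(l=%g,s=%g,phi=%g)", l, s, phi)
  }
  p <- zd_probabilities(l, s, phi, payoffs)
  new_strategy(name, "reactive1", first_move = first_move,
               p = unname(p), l = l, s = s, phi = phi)
}

#' Generic memory-one stochastic strategy
#'
#' @param p cooperation probabilities `c(p_CC, p_CD, p_DC, p_DD)` indexed
#'   by (own last action, opponent last action).
#' @param first_move first-move rule.
#' @param name label.
#' @return An `ipd_strategy`.
#' @export
reactive1_strategy <- function(p, first_move = "random", name = "reactive1") {
  p <- as.numeric(p)
  if (length(p) != 4 || any(p < 0 | p > 1))
    stop("p must be four probabilities in [0, 1]")
  new_strategy(name, "reactive1", first_move = first_move, p = p)
}

#' Deterministic lookup-table strategy over the history-state codec
#'
#' @param table vector of actions (`"C"`/`"D"` or 0/1), one per state in
#'   the canonical codec ordering (see [state_codec()]).
#' @param memory memory length matching the table size.
#' @param first_move first-move rule.
#' @param name label.
#' @return An `ipd_strategy`.
#' @export
table_strategy <- function(table, memory = 2L, first_move = "random",
                           name = "table") {
  tab <- action_code(table)
  n <- count_states(2L, memory)
  if (length(tab) != n)
    stop(sprintf("table must cover all %d states (got %d)", n, length(tab)))
  new_strategy(name, "table", first_move = first_move,
               table = tab, memory = as.integer(memory))
}

#' The memory-two bilateral reciprocity (MTBR) strategy
#'
#' A deterministic memory-two lookup table over the 20-state codec,
#' summarized by three rules: (i) after a round in which the opponent
#' defected while MTBR cooperated and only one round of history exists,
#' MTBR keeps cooperating (forgiving an opening defection); (ii) after
#' two consecutive rounds of mutual defection MTBR switches to
#' cooperation to break the deadlock; (iii) in every other state MTBR
#' copies the opponent's last action.
#'
#' @param first_move first-move rule (default fair coin).
#' @return A `table` `ipd_strategy` named `"MTBR"`.
#' @examples
#' s <- mtbr_strategy()
#' # state (opp = D, own = C) in round 2 -> cooperate
#' s$table[encode_state(rbind(c(opp = 1, own = 0))) + 1]
#' @export
mtbr_strategy <- function(first_move = "random") {
  codec <- state_codec(2L, 2L)
  tab <- integer(codec$n_states)
  for (idx in seq_len(codec$n_states) - 1L) {
    h <- decode_state(idx, codec)
    k <- nrow(h)
    opp_last <- h[k, "opp"]; own_last <- h[k, "own"]
    if (k == 1L && opp_last == 1L && own_last == 0L) {
      tab[idx + 1L] <- 0L                       # rule (i): forgive
    } else if (k == 2L && all(h == 1L)) {
      tab[idx + 1L] <- 0L                       # rule (ii): break deadlock
    } else {
      tab[idx + 1L] <- opp_last                 # rule (iii): mirror
    }
  }
  table_strategy(tab, memory = 2L, first_move = first_move, name = "MTBR")
}

#' Stationary per-round payoffs of two memory-one strategies
#'
#' Treats the joint last-round action pair as a four-state Markov chain
#' (states CC, CD, DC, DD from the first player's perspective) and
#' returns both players' expected per-round payoffs under its stationary
#' distribution. Degenerate (0/1) transition probabilities are perturbed
#' by 1e-9 so the chain has a unique stationary distribution; this is the
#' standard independence oracle for checking the ZD payoff relation.
#'
#' @param p,q cooperation probability vectors `c(p_CC, p_CD, p_DC, p_DD)`
#'   for the two players (each indexed by own then opponent's last
#'   action), or `reactive1` strategies.
#' @param payoffs a [payoff_params()].
#' @return `c(payoff_p, payoff_q)`.
#' @export
stationary_payoffs <- function(p, q, payoffs = evaluation_payoffs()) {
  if (inherits(p, "ipd_strategy")) p <- p$p
  if (inherits(q, "ipd_strategy")) q <- q$p
  eps <- 1e-9
  p <- pmin(pmax(as.numeric(p), eps), 1 - eps)
  q <- pmin(pmax(as.numeric(q), eps), 1 - eps)
  # states from p's view: 1 CC, 2 CD, 3 DC, 4 DD (own, opp)
  # q's view of state s: own = opp(s), opp = own(s) -> q index swaps CD/DC
  qv <- q[c(1, 3, 2, 4)]
  Tm <- matrix(0, 4, 4)
  for (s in 1:4) {
    pc <- p[s]; qc <- qv[s]
    Tm[s, ] <- c(pc * qc, pc * (1 - qc), (1 - pc) * qc, (1 - pc) * (1 - qc))
  }
  A <- t(Tm) - diag(4)
  A[4, ] <- 1
  pi_st <- solve(A, c(0, 0, 0, 1))
  if (any(!is.finite(pi_st)))
    stop("degenerate chain: no unique stationary distribution")
  pv <- payoff_vector(payoffs)          # R S T P for (CC, CD, DC, DD)
  c(sum(pi_st * pv), sum(pi_st * pv[c(1, 3, 2, 4)]))
}

#' Strategy rosters
#'
#' `roster_set1()` is the seven-mentor benchmark set (GradualTFT,
#' OmegaTFT, TFT, GTFT0.3, FoolMeOnce, WSLS, HoldAGrudge);
#' `roster_set2()` adds the eight zero-determinant strategies (15 in
#' total). `make_roster()` resolves a roster by name (`"set1"`,
#' `"set2"`, optionally with `"+MTBR"`) or builds one from a character
#' vector of strategy names.
#'
#' @param payoffs a [payoff_params()] (used by WSLS and the ZD
#'   derivations).
#' @return A named list of `ipd_strategy` objects.
#' @export
roster_set1 <- function(payoffs = evaluation_payoffs()) {
  stats::setNames(lapply(MENTOR_NAMES, make_mentor, payoffs = payoffs),
                  MENTOR_NAMES)
}

#' @rdname roster_set1
#' @export
roster_set2 <- function(payoffs = evaluation_payoffs()) {
  zd <- stats::setNames(
    lapply(names(ZD_PRESETS), zd_strategy, payoffs = payoffs),
    names(ZD_PRESETS))
  c(roster_set1(payoffs), zd)
}

#' @rdname roster_set1
#' @param spec roster name (`"set1"`, `"set2"`, `"set1+MTBR"`,
#'   `"set2+MTBR"`) or a character vector of strategy names.
#' @export
make_roster <- function(spec, payoffs = evaluation_payoffs()) {
  if (length(spec) == 1 && spec %in%
        c("set1", "set2", "set1+MTBR", "set2+MTBR")) {
    base <- if (startsWith(spec, "set1")) roster_set1(payoffs)
            else roster_set2(payoffs)
    if (endsWith(spec, "+MTBR")) base$MTBR <- mtbr_strategy()
    return(base)
  }
  stats::setNames(lapply(spec, strategy_by_name, payoffs = payoffs), spec)
}

#' Resolve a single strategy by name
#'
#' @param name a mentor name, ZD preset name, `"MTBR"`, `"AllC"` or
#'   `"AllD"`.
#' @param payoffs a [payoff_params()].
#' @return An `ipd_strategy`.
#' @export
strategy_by_name <- function(name, payoffs = evaluation_payoffs()) {
  if (name == "MTBR") return(mtbr_strategy())
  if (name %in% names(ZD_PRESETS)) return(zd_strategy(name, payoffs))
  make_mentor(name, payoffs)
}

#' Serialize a roster to a JSON description
#'
#' Table strategies are written as action strings over the canonical
#' state ordering (for memory two, the 20 states of [state_codec()]).
#'
#' @param roster a named list of strategies.
#' @return A JSON string.
#' @export
roster_json <- function(roster) {
  desc <- lapply(roster, function(s) {
    out <- list(name = s$name, kind = s$kind, first_move = s$first_move)
    if (s$kind == "table")
      out$table <- paste(action_label(s$table), collapse = "")
    if (s$kind == "reactive1") out$p <- s$p
    if (s$kind == "gtft") out$g <- s$g
    out
  })
  jsonlite::toJSON(desc, auto_unbox = TRUE, digits = NA)
}
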