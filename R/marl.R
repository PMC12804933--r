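# Tabular multi-agent Q-learning: win/lose-conditioned round rewards,
# Bellman updates, epsilon-greedy action selection, and the training loop
# that plays learning agents against a mixed pool of agents and mentors.

#' Hyperparameters of the multi-agent Q-learning trainer
#'
#' @param alpha learning rate in (0, 1].
#' @param gamma discount factor in \[0, 1).
#' @param theta payoff-versus-winning weight in \[0, 1\]: the per-round
#'   reward is `theta * U_t` plus, only when the agent's match average
#'   weakly beats the opponent's, `(1 - theta) * mean(U)`.
#' @param epsilon exploration rate of the epsilon-greedy policy.
#' @param i_total number of training iterations (one match each).
#' @param n_agents number of learning agents.
#' @param n_mentors number of mentor slots (sets the default opponent
#'   mix).
#' @param mentor_prob probability that an opponent draw is a mentor;
#'   defaults to `n_mentors / (n_agents + n_mentors)`.
#' @param memory agent memory length `l`.
#' @param q_init `"zeros"` (default) or `"uniform"` (entries drawn
#'   uniformly from \[0, `q_init_range`\]).
#' @param q_init_range upper bound of the uniform initialization.
#' @return An object of class `learning_params`.
#' @export
learning_params <- function(alpha = 0.2, gamma = 0.5, theta = 0.8,
                            epsilon = 0.1, i_total = 2e6,
                            n_agents = 49L, n_mentors = 49L,
                            mentor_prob = NULL, memory = 2L,
                            q_init = c("zeros", "uniform"),
                            q_init_range = 1) {
  stopifnot(alpha > 0, alpha <= 1, gamma >= 0, gamma < 1,
            theta >= 0, theta <= 1, epsilon >= 0, epsilon <= 1,
            i_total >= 1, n_agents >= 1, memory >= 1)
  if (is.null(mentor_prob)) mentor_prob <- n_mentors / (n_agents + n_mentors)
  stopifnot(mentor_prob >= 0, mentor_prob <= 1)
  structure(list(alpha = alpha, gamma = gamma, theta = theta,
                 epsilon = epsilon, i_total = i_total,
                 n_agents = as.integer(n_agents),
                 n_mentors = as.integer(n_mentors),
                 mentor_prob = mentor_prob, memory = as.integer(memory),
                 q_init = match.arg(q_init), q_init_range = q_init_range),
            class = "learning_params")
}

#' Win/lose-conditioned per-round reward
#'
#' The learning signal for one round blends the round payoff `u_t` with
#' the agent's match-average payoff, but only pays the average component
#' out when the agent is (weakly) winning the match:
#' `theta * u_t + (1 - theta) * mean_self` if `mean_self >= mean_opp`,
#' else `theta * u_t`.
#'
#' @param u_t the round payoff.
#' @param mean_self,mean_opp match-average payoffs of the agent and its
#'   opponent.
#' @param theta weight in \[0, 1\].
#' @return The scalar reward.
#' @examples
#' round_reward(3, 2.5, 2.0, 0.8)  # winning branch: 2.9
#' round_reward(5, 1.0, 2.0, 0.8)  # losing branch: 4.0
#' @export
round_reward <- function(u_t, mean_self, mean_opp, theta) {
  stopifnot(theta >= 0, theta <= 1)
  theta * u_t + ifelse(mean_self >= mean_opp, (1 - theta) * mean_self, 0)
}

#' Q-table over the history-state codec
#'
#' @param codec a [state_codec()].
#' @param init `"zeros"` or `"uniform"`.
#' @param init_range upper bound for uniform initialization.
#' @return An `n_states x 2` matrix of class `q_table` with columns `C`,
#'   `D` and the codec attached as an attribute.
#' @export
q_table <- function(codec = state_codec(), init = c("zeros", "uniform"),
                    init_range = 1) {
  init <- match.arg(init)
  n <- codec$n_states
  vals <- if (init == "zeros") matrix(0, n, 2)
          else matrix(stats::runif(2 * n, 0, init_range), n, 2)
  colnames(vals) <- c("C", "D")
  structure(vals, codec = codec, class = c("q_table", "matrix", "array"))
}

#' Single-entry Bellman update
#'
#' `Q(s, a) <- Q(s, a) + alpha * (w + gamma * max_a' Q(s', a') - Q(s, a))`;
#' every other entry is left unchanged.
#'
#' @param q a `q_table` (or plain matrix with columns C, D).
#' @param s zero-based state index of the updated entry.
#' @param a action taken (`"C"`/`"D"` or 0/1).
#' @param w the round reward.
#' @param s_next zero-based index of the successor state.
#' @param alpha learning rate.
#' @param gamma discount factor.
#' @return The updated table.
#' @export
q_update <- function(q, s, a, w, s_next, alpha, gamma) {
  n <- nrow(q)
  if (s < 0 || s >= n || s_next < 0 || s_next >= n)
    stop("state index out of range")
  ai <- action_code(a) + 1L
  target <- w + gamma * max(q[s_next + 1L, ])
  q[s + 1L, ai] <- q[s + 1L, ai] + alpha * (target - q[s + 1L, ai])
  q
}

#' Epsilon-greedy action selection
#'
#' With probability `1 - epsilon` returns the argmax action (ties broken
#' toward `C`, the lowest action index); with probability `epsilon` a
#' uniform-random action.
#'
#' @param q_row length-2 vector of Q-values `(C, D)`.
#' @param epsilon exploration rate.
#' @return `"C"` or `"D"`.
#' @export
select_action <- function(q_row, epsilon = 0) {
  if (epsilon > 0 && stats::runif(1) < epsilon)
    return(sample(c("C", "D"), 1))
  if (q_row[2] > q_row[1]) "D" else "C"
}

#' Train learning agents by multi-agent Q-learning
#'
#' Runs the training loop: each iteration draws a learning agent and an
#' opponent (a mentor with probability `mentor_prob`, otherwise another
#' agent), plays one repeated match with random first moves, computes the
#' match-average payoffs and the win/lose-conditioned reward
#' ([round_reward()]) for every round with a defined history state
#' (rounds 2..L), and applies Bellman updates in ascending round order
#' for each learning seat. The round-L update bootstraps from the state
#' produced by round L.
#'
#' @param learning a [learning_params()].
#' @param match a [match_config()] (default 20 rounds, no noise).
#' @param payoffs a [payoff_params()]; training default is
#'   [training_payoffs()].
#' @param mentor_roster list of mentor strategies (defaults to the seven
#'   benchmark mentors).
#' @return A list of `q_table` objects, one per agent.
#' @examples
#' set.seed(1)
#' q <- train(learning_params(i_total = 500, n_agents = 2, n_mentors = 1),
#'            mentor_roster = list(make_mentor("TFT")))
#' dim(q[[1]])
#' @export
train <- function(learning = learning_params(),
                  match = match_config(rounds = 20L),
                  payoffs = training_payoffs(),
                  mentor_roster = roster_set1(payoffs)) {
  if (learning$mentor_prob > 0 && length(mentor_roster) == 0)
    stop("mentor_prob > 0 requires a non-empty mentor roster")
  specs <- lapply(mentor_roster, strategy_spec)
  init_range <- if (learning$q_init == "uniform") learning$q_init_range else 0
  qs <- cpp_train(learning$n_agents, learning$i_total, match$rounds,
                  match$noise, payoff_vector(payoffs), learning$alpha,
                  learning$gamma, learning$theta, learning$epsilon,
                  learning$memory, unname(specs), learning$mentor_prob,
                  init_range)
  codec <- state_codec(2L, learning$memory)
  lapply(qs, function(m) {
    colnames(m) <- c("C", "D")
    structure(m, codec = codec, class = c("q_table", "matrix", "array"))
  })
}

#' Extract the greedy policy from a Q-table
#'
#' @param q a `q_table`.
#' @param first_move first-move rule of the extracted strategy.
#' @return A deterministic [table_strategy()] choosing the argmax action
#'   in every state (ties broken toward `C`).
#' @export
extract_policy <- function(q, first_move = "random") {
  codec <- attr(q, "codec")
  if (is.null(codec)) codec <- state_codec(2L, memory_from_states(nrow(q)))
  acts <- ifelse(q[, 2] > q[, 1], 1L, 0L)
  table_strategy(acts, memory = codec$memory, first_move = first_move,
                 name = "greedy-policy")
}

memory_from_states <- function(n_states) {
  m <- 1L
  while (count_states(2L, m) < n_states) m <- m + 1L
  if (count_states(2L, m) != n_states)
    stop("table length does not match any memory length")
  m
}

#' Per-state agreement of two table strategies
#'
#' @param a,b `table` strategies over the same codec.
#' @return Fraction of states on which the two tables choose the same
#'   action.
#' @export
policy_agreement <- function(a, b) {
  stopifnot(a$kind == "table", b$kind == "table",
            length(a$table) == length(b$table))
  mean(a$table == b$table)
}

#' Serialize a Q-table to CSV
#'
#' Writes one row per state with a readable state label (oldest round
#' first, `opp/own` pairs) and the per-action values.
#'
#' @param q a `q_table`.
#' @param path output file.
#' @return The written data frame, invisibly.
#' @export
write_q_table <- function(q, path) {
  codec <- attr(q, "codec")
  labels <- vapply(seq_len(nrow(q)) - 1L, function(i) {
    h <- decode_state(i, codec)
    paste(apply(h, 1, function(r)
      paste0(action_label(r["opp"]), action_label(r["own"]))),
      collapse = "|")
  }, character(1))
  df <- data.frame(state = seq_len(nrow(q)) - 1L, history = labels,
                   Q_C = q[, 1], Q_D = q[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
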