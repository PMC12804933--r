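# Agent-based evolutionary dynamics: Fermi-rule imitation with mutation
# on well-mixed, lattice, and Barabasi-Albert populations, plus the
# greediness/unfear game-type sweep.

#' Configuration of an evolving population
#'
#' @param roster named list of strategies forming the pool (see
#'   [make_roster()]).
#' @param n population size `N` (must be a perfect square for lattices).
#' @param delta selection intensity of the Fermi rule.
#' @param mu mutation probability: per elementary event the focal
#'   individual adopts a uniform-random pool strategy with probability
#'   `mu` instead of imitating.
#' @param network `"complete"` (well-mixed), `"lattice"` (non-periodic
#'   4-neighbor grid) or `"ba"` (Barabasi-Albert with attachment
#'   parameter `ba_m`, average degree about `2 * ba_m`).
#' @param ba_m Barabasi-Albert attachment parameter (default 2, average
#'   degree about 4).
#' @param payoffs a [payoff_params()].
#' @param match a [match_config()] used whenever matches are sampled.
#' @param steps number of elementary imitation events to run.
#' @param payoff_mode `"matrix"` (mean-field payoffs from a pairwise
#'   payoff matrix, default and only mode for complete graphs) or
#'   `"sampled"` (literal matches each event; always used on networks,
#'   where payoffs average over matches against all current neighbors).
#' @param n_reps_matrix Monte-Carlo repetitions per pair when the payoff
#'   matrix has to be estimated.
#' @param record_stride events between recorded trajectory points
#'   (default `n`, i.e. one epoch).
#' @param burn_in events discarded before time-averaging frequencies.
#' @param payoff_matrix optional precomputed [estimate_payoff_matrix()]
#'   result (rows/columns must match the roster).
#' @param initial_counts optional initial per-strategy counts (defaults
#'   to a uniform-random assignment).
#' @return An object of class `evolution_config`.
#' @export
evolution_config <- function(roster, n = 500L, delta = 3, mu = 0,
                             network = c("complete", "lattice", "ba"),
                             ba_m = 2L,
                             payoffs = evaluation_payoffs(),
                             match = match_config(),
                             steps = 1e5, payoff_mode = NULL,
                             n_reps_matrix = 10000L,
                             record_stride = NULL, burn_in = 0,
                             payoff_matrix = NULL,
                             initial_counts = NULL) {
  network <- match.arg(network)
  stopifnot(delta >= 0, mu >= 0, mu <= 1, n >= 2)
  if (network == "lattice" && round(sqrt(n))^2 != n)
    stop("lattice populations need a perfect-square N")
  if (is.null(payoff_mode))
    payoff_mode <- if (network == "complete") "matrix" else "sampled"
  payoff_mode <- match.arg(payoff_mode, c("matrix", "sampled"))
  if (network != "complete" && payoff_mode == "matrix")
    stop("matrix-mode payoffs are only defined for well-mixed populations")
  if (is.null(record_stride)) record_stride <- as.integer(n)
  structure(list(roster = roster, n = as.integer(n), delta = delta, mu = mu,
                 network = network, ba_m = as.integer(ba_m),
                 payoffs = payoffs, match = match, steps = steps,
                 payoff_mode = payoff_mode,
                 n_reps_matrix = as.integer(n_reps_matrix),
                 record_stride = as.integer(record_stride),
                 burn_in = burn_in, payoff_matrix = payoff_matrix,
                 initial_counts = initial_counts),
            class = "evolution_config")
}

#' Fermi imitation probability
#'
#' Probability that individual `i` (mean payoff `mean_i`) copies the
#' strategy of individual `j`:
#' `1 / (1 + exp(delta * (mean_i - mean_j)))`. Equal payoffs give 1/2
#' for any selection intensity, and `delta = 0` makes imitation a coin
#' flip regardless of payoffs.
#'
#' @param mean_i,mean_j average payoffs of the focal and model players.
#' @param delta selection intensity, `>= 0`.
#' @return Imitation probability in (0, 1).
#' @export
imitation_probability <- function(mean_i, mean_j, delta) {
  stopifnot(delta >= 0)
  1 / (1 + exp(delta * (mean_i - mean_j)))
}

#' Build an initial population state
#'
#' Assigns each individual a uniform-random pool strategy (or a fixed
#' composition via `initial_counts`) and constructs the interaction
#' structure: a complete graph, a non-periodic `sqrt(N) x sqrt(N)`
#' 4-neighbor lattice, or a Barabasi-Albert scale-free graph.
#'
#' @param config an [evolution_config()].
#' @return A `population_state`: `assignment` (strategy index per
#'   individual), `counts`, `graph` (an \pkg{igraph} object, or `NULL`
#'   for complete graphs), `neighbors` (adjacency list, `NULL` for
#'   complete graphs).
#' @export
build_population <- function(config) {
  n <- config$n
  k <- length(config$roster)
  assignment <- if (!is.null(config$initial_counts)) {
    stopifnot(sum(config$initial_counts) == n)
    sample(rep.int(seq_len(k), config$initial_counts))
  } else {
    sample.int(k, n, replace = TRUE)
  }
  graph <- switch(config$network,
    complete = NULL,
    lattice = igraph::make_lattice(rep(as.integer(sqrt(n)), 2),
                                   periodic = FALSE),
    ba = igraph::sample_pa(n, m = config$ba_m, directed = FALSE)
  )
  neighbors <- if (is.null(graph)) NULL
               else lapply(seq_len(n), function(v)
                 as.integer(igraph::neighbors(graph, v)))
  structure(list(assignment = assignment,
                 counts = tabulate(assignment, nbins = k),
                 graph = graph, neighbors = neighbors),
            class = "population_state")
}

# Mean payoff of one individual: matrix mode uses the finite-population
# mean-field formula; sampled mode plays fresh matches (against a random
# partner on complete graphs, against every neighbor on networks).
individual_payoff <- function(idx, state, config, A, n_samples = 1L) {
  s <- state$assignment[idx]
  if (config$payoff_mode == "matrix") {
    u <- finite_population_payoffs(state$counts, A, config$n)
    return(u[s])
  }
  strat <- config$roster[[s]]
  if (is.null(state$neighbors)) {
    partners <- sample(setdiff(seq_len(config$n), idx), n_samples,
                       replace = TRUE)
  } else {
    partners <- state$neighbors[[idx]]
    if (length(partners) == 0) return(NA_real_)
  }
  mean(vapply(partners, function(p) {
    play_match(strat, config$roster[[state$assignment[p]]],
               config$match, config$payoffs)$mean_a
  }, numeric(1)))
}

#' One elementary imitation event
#'
#' Picks a focal individual uniformly; with probability `mu` it adopts a
#' uniform-random pool strategy, otherwise a model individual is drawn
#' (uniformly over all others on complete graphs, over the focal
#' player's neighbors on networks) and the focal player imitates the
#' model's strategy with the Fermi probability computed from their mean
#' payoffs.
#'
#' @param state a `population_state`.
#' @param config an [evolution_config()].
#' @param A payoff matrix (required in matrix mode; estimated by
#'   [run_evolution()] when absent).
#' @return The updated `population_state`.
#' @export
evolution_step <- function(state, config, A = NULL) {
  i <- sample.int(config$n, 1)
  k <- length(config$roster)
  if (config$mu > 0 && stats::runif(1) < config$mu) {
    new_s <- sample.int(k, 1)
    state$counts[state$assignment[i]] <- state$counts[state$assignment[i]] - 1L
    state$counts[new_s] <- state$counts[new_s] + 1L
    state$assignment[i] <- new_s
    return(state)
  }
  if (is.null(state$neighbors)) {
    j <- sample(setdiff(seq_len(config$n), i), 1)
  } else {
    nb <- state$neighbors[[i]]
    if (length(nb) == 0) {
      warning("isolated focal node; event skipped")
      return(state)
    }
    j <- if (length(nb) == 1) nb else sample(nb, 1)
  }
  if (state$assignment[i] != state$assignment[j]) {
    ui <- individual_payoff(i, state, config, A)
    uj <- individual_payoff(j, state, config, A)
    if (is.finite(ui) && is.finite(uj) &&
        stats::runif(1) < imitation_probability(ui, uj, config$delta)) {
      state$counts[state$assignment[i]] <-
        state$counts[state$assignment[i]] - 1L
      state$counts[state$assignment[j]] <-
        state$counts[state$assignment[j]] + 1L
      state$assignment[i] <- state$assignment[j]
    }
  }
  state
}

#' Run an evolutionary trajectory
#'
#' Iterates elementary imitation events, recording strategy frequencies
#' and the population-average payoff every `record_stride` events (one
#' epoch = `N` events). Well-mixed matrix-mode runs use a fast compiled
#' path; sampled-mode and network runs use the literal per-event
#' procedure. Runs stop early once the population is monomorphic and
#' mutation is off.
#'
#' @param config an [evolution_config()].
#' @return An `evolution_result` list: `trajectory` (data frame with
#'   `epoch`, `strategy`, `frequency`, `mean_payoff`), `final_counts`,
#'   `avg_freq` (post-burn-in time-averaged frequencies, matrix mode),
#'   `events`, and the payoff matrix used (matrix mode).
#' @export
run_evolution <- function(config) {
  k <- length(config$roster)
  nms <- names(config$roster)
  A <- config$payoff_matrix
  if (config$payoff_mode == "matrix" && is.null(A))
    A <- estimate_payoff_matrix(config$roster, config$payoffs,
                                config$match, config$n_reps_matrix)
  if (!is.null(A)) stopifnot(nrow(A) == k)

  if (config$network == "complete" && config$payoff_mode == "matrix") {
    counts0 <- config$initial_counts %||%
      tabulate(sample.int(k, config$n, replace = TRUE), nbins = k)
    res <- cpp_evolve_matrix(unclass(A), as.integer(counts0), config$delta,
                             config$mu, config$steps, config$record_stride,
                             config$burn_in, TRUE)
    traj <- res$trajectory
    colnames(traj) <- nms
    df <- data.frame(
      epoch = rep(res$traj_event / config$n, times = k),
      strategy = rep(nms, each = nrow(traj)),
      frequency = as.vector(traj),
      mean_payoff = rep(res$traj_payoff, times = k),
      stringsAsFactors = FALSE)
    return(structure(list(trajectory = df,
                          final_counts = stats::setNames(res$final_counts, nms),
                          avg_freq = stats::setNames(res$avg_freq, nms),
                          events = res$events_run, payoff_matrix = A),
                     class = "evolution_result"))
  }

  state <- build_population(config)
  n_rec <- floor(config$steps / config$record_stride) + 1
  rec_freq <- matrix(NA_real_, n_rec, k)
  rec_epoch <- rec_pay <- numeric(n_rec)
  rec <- 1L
  record <- function(ev) {
    rec_freq[rec, ] <<- state$counts / config$n
    rec_epoch[rec] <<- ev / config$n
    rec_pay[rec] <<- if (config$payoff_mode == "matrix") {
      u <- finite_population_payoffs(state$counts, A, config$n)
      sum(state$counts * ifelse(is.na(u), 0, u)) / config$n
    } else NA_real_
    rec <<- rec + 1L
  }
  record(0)
  ev <- 0
  while (ev < config$steps) {
    ev <- ev + 1
    state <- evolution_step(state, config, A)
    if (ev %% config$record_stride == 0) record(ev)
    if (config$mu == 0 && max(state$counts) == config$n) break
  }
  used <- seq_len(rec - 1L)
  df <- data.frame(
    epoch = rep(rec_epoch[used], times = k),
    strategy = rep(nms, each = length(used)),
    frequency = as.vector(rec_freq[used, , drop = FALSE]),
    mean_payoff = rep(rec_pay[used], times = k),
    stringsAsFactors = FALSE)
  structure(list(trajectory = df,
                 final_counts = stats::setNames(state$counts, nms),
                 avg_freq = NULL, events = ev, payoff_matrix = A,
                 state = state),
            class = "evolution_result")
}

#' Sweep game types over the greediness/unfear plane
#'
#' For each `(T, S)` cell (with `R` and `P` fixed) the roster is rebuilt
#' for the cell's payoffs (zero-determinant presets that become
#' infeasible for a cell are dropped and recorded), the pairwise payoff
#' matrix is re-estimated, and `reps` well-mixed matrix-mode runs are
#' executed. Reported per cell: the game-type label, mean final MTBR
#' fraction, mean cooperation-weighted payoff, and the strategies
#' dropped.
#'
#' @param base an [evolution_config()] whose roster contains an `"MTBR"`
#'   entry; its `n`, `delta`, `mu`, `steps` and estimation settings are
#'   reused per cell.
#' @param t_values,s_values grids of temptation and sucker payoffs.
#' @param reps evolutionary runs per cell.
#' @param roster_names names used to rebuild the roster per cell
#'   (defaults to the names of `base$roster`).
#' @return A data frame with one row per cell: `T`, `S`, `game_type`,
#'   `mtbr_fraction`, `mean_payoff`, `n_strategies`, `dropped`.
#' @export
sweep_games <- function(base, t_values, s_values, reps = 3L,
                        roster_names = names(base$roster)) {
  rows <- list()
  for (Tv in t_values) for (Sv in s_values) {
    pp <- payoff_params(R = base$payoffs$R, S = Sv, T = Tv, P = base$payoffs$P)
    roster <- list()
    dropped <- character(0)
    for (nm in roster_names) {
      s <- tryCatch(strategy_by_name(nm, pp), error = function(e) NULL)
      if (is.null(s)) dropped <- c(dropped, nm) else roster[[nm]] <- s
    }
    cfg <- evolution_config(roster, n = base$n, delta = base$delta,
                            mu = base$mu, payoffs = pp, match = base$match,
                            steps = base$steps,
                            n_reps_matrix = base$n_reps_matrix,
                            record_stride = base$record_stride,
                            burn_in = base$burn_in)
    A <- estimate_payoff_matrix(roster, pp, base$match, base$n_reps_matrix)
    mtbr_fracs <- pays <- numeric(reps)
    for (r in seq_len(reps)) {
      cfg$payoff_matrix <- A
      res <- run_evolution(cfg)
      fin <- res$final_counts / base$n
      mtbr_fracs[r] <- if ("MTBR" %in% names(fin)) fin[["MTBR"]] else 0
      tr <- res$trajectory
      pays[r] <- tr$mean_payoff[which.max(tr$epoch)]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      T = Tv, S = Sv, game_type = classify_game(pp),
      mtbr_fraction = mean(mtbr_fracs), mean_payoff = mean(pays),
      n_strategies = length(roster),
      dropped = paste(dropped, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
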