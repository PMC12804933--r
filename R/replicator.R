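# Deterministic evolutionary predictions: pairwise payoff-matrix
# estimation, finite-population average payoffs, and replicator-equation
# integration on the probability simplex.

#' Estimate the pairwise match payoff matrix of a roster
#'
#' Entry `a_ij` is the expected per-round match payoff of an
#' `i`-strategist against a `j`-strategist in a repeated match with
#' random first moves. Stochastic pairs are estimated by Monte Carlo
#' (`n_reps` matches per unordered pair, each match yielding both
#' directions); for noise-free deterministic pairs the expectation can be
#' computed exactly by enumerating the equiprobable first-move profiles
#' (`exact_deterministic = TRUE`, flagged per-entry in the `exact`
#' attribute).
#'
#' @param roster named list of strategies (see [make_roster()]).
#' @param payoffs a [payoff_params()].
#' @param config a [match_config()].
#' @param n_reps Monte-Carlo repetitions per pair.
#' @param exact_deterministic use first-move enumeration for
#'   deterministic pairs.
#' @return A `payoff_matrix`: the `n x n` matrix with strategy names,
#'   plus attributes `se` (standard errors), `exact` (logical matrix) and
#'   `meta` (estimation metadata).
#' @export
estimate_payoff_matrix <- function(roster, payoffs = evaluation_payoffs(),
                                   config = match_config(),
                                   n_reps = 10000L,
                                   exact_deterministic = TRUE) {
  n <- length(roster)
  nms <- names(roster)
  A <- SE <- matrix(0, n, n, dimnames = list(nms, nms))
  EX <- matrix(FALSE, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n)) for (j in i:n) {
    si <- roster[[i]]; sj <- roster[[j]]
    exact <- exact_deterministic && config$noise == 0 &&
      is_deterministic(si) && is_deterministic(sj)
    est <- if (exact) exact_match_payoffs(si, sj, config, payoffs)
           else expected_match_payoffs(si, sj, config, payoffs, n_reps)
    A[i, j] <- est$mean_a; A[j, i] <- est$mean_b
    SE[i, j] <- est$se_a; SE[j, i] <- est$se_b
    EX[i, j] <- EX[j, i] <- exact
  }
  structure(A, se = SE, exact = EX,
            meta = list(n_reps = n_reps, rounds = config$rounds,
                        noise = config$noise,
                        payoffs = unlist(payoffs[c("R", "S", "T", "P")])),
            class = c("payoff_matrix", "matrix", "array"))
}

#' Finite-population average payoffs
#'
#' With `X_i` individuals of strategy `i` in a well-mixed population of
#' `N` players, an `i`-strategist's expected payoff excludes
#' self-interaction:
#' `Ubar_i = (a_i1 X_1 + ... + a_ii (X_i - 1) + ... + a_in X_n) / (N - 1)`.
#'
#' @param counts integer vector of per-strategy counts summing to `n`.
#' @param a payoff matrix.
#' @param n population size `N` (defaults to `sum(counts)`).
#' @return Per-strategy mean payoffs (`NA` where `X_i = 0`).
#' @export
finite_population_payoffs <- function(counts, a, n = sum(counts)) {
  if (n < 2) stop("population size must be at least 2")
  stopifnot(sum(counts) == n, length(counts) == nrow(a))
  u <- (as.vector(a %*% counts) - diag(as.matrix(a))) / (n - 1)
  u[counts == 0] <- NA_real_
  u
}

#' Right-hand side of the replicator equation
#'
#' `xdot_i = delta * N / (2 * (N - 1)) * x_i * (Ubar_i - Ubar)` with
#' payoffs in the large-population limit `Ubar_i = (A x)_i` and
#' `Ubar = x' A x`. The prefactor only rescales time; `n = Inf` gives
#' the limit factor `delta / 2`.
#'
#' @param x frequency vector on the simplex.
#' @param a payoff matrix.
#' @param delta selection intensity.
#' @param n population size (finite values only change the time scale).
#' @return The rate vector, which sums to zero.
#' @export
replicator_rhs <- function(x, a, delta = 1, n = Inf) {
  u <- as.vector(a %*% x)
  ubar <- sum(x * u)
  pref <- if (is.finite(n)) delta * n / (2 * (n - 1)) else delta / 2
  pref * x * (u - ubar)
}

#' Integrate the replicator equation to equilibrium
#'
#' Adaptive ODE integration (via \pkg{deSolve}) in chunks, renormalizing
#' the state onto the simplex between chunks, until the largest rate
#' falls below `tol` or `t_max` is reached.
#'
#' @param x0 initial frequencies (renormalized onto the simplex).
#' @param a payoff matrix.
#' @param delta selection intensity (a pure time rescale).
#' @param n population size entering the time-scale prefactor.
#' @param tol equilibrium tolerance on `max(abs(xdot))`.
#' @param t_max maximum integration time.
#' @param chunk time per integration chunk.
#' @param extinction_cutoff frequencies below this are zeroed between
#'   chunks (0 disables; useful to accelerate very long transients).
#' @return A list: `x` (terminal frequencies), `mean_payoff`
#'   (`x' A x`), `converged`, `t`, and `trajectory` (matrix of recorded
#'   states with a `time` column).
#' @examples
#' a <- matrix(c(3, 0, 5, 1), 2, 2, byrow = TRUE,
#'             dimnames = list(c("C", "D"), c("C", "D")))
#' eq <- integrate_to_equilibrium(c(0.5, 0.5), a)
#' eq$x  # defection fixates in the one-shot PD
#' @export
integrate_to_equilibrium <- function(x0, a, delta = 1, n = Inf,
                                     tol = 1e-10, t_max = 1e5,
                                     chunk = 250, extinction_cutoff = 0) {
  x <- pmax(as.numeric(x0), 0)
  if (sum(x) <= 0) stop("x0 must have positive mass")
  x <- x / sum(x)
  am <- unclass(a)
  rhs <- function(t, state, parms) {
    list(replicator_rhs(pmax(state, 0), am, delta, n))
  }
  t_now <- 0
  traj <- matrix(c(0, x), nrow = 1)
  converged <- max(abs(replicator_rhs(x, am, delta, n))) < tol
  while (!converged && t_now < t_max) {
    t_end <- min(t_now + chunk, t_max)
    sol <- deSolve::ode(y = x, times = c(t_now, t_end), func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    x <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    if (extinction_cutoff > 0) x[x < extinction_cutoff] <- 0
    x <- x / sum(x)
    t_now <- t_end
    traj <- rbind(traj, c(t_now, x))
    converged <- max(abs(replicator_rhs(x, am, delta, n))) < tol
  }
  colnames(traj) <- c("time", rownames(a) %||% paste0("s", seq_along(x)))
  names(x) <- rownames(a)
  list(x = x, mean_payoff = as.numeric(t(x) %*% am %*% x),
       converged = converged, t = t_now, trajectory = traj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a payoff matrix and its metadata
#'
#' The matrix goes to `<path>.csv` (strategy names as header row and
#' column) and the estimation metadata (repetitions, rounds, noise,
#' payoffs) to `<path>.json`.
#'
#' @param a a `payoff_matrix`.
#' @param path output path without extension.
#' @return The CSV path, invisibly.
#' @export
write_payoff_matrix <- function(a, path) {
  csv <- paste0(path, ".csv")
  utils::write.csv(as.data.frame(unclass(a)), csv, row.names = TRUE)
  jsonlite::write_json(attr(a, "meta"), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}
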