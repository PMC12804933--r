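# Shared fixtures and independent oracles used across test files.

# Round index of the first mutual cooperation in a match (Inf if none).
first_mutual_coop <- function(m) {
  idx <- which(m$actions_a == "C" & m$actions_b == "C")
  if (length(idx) == 0) Inf else idx[1]
}

# Independent pure-R reference simulator for deterministic lookup-table
# strategies with forced first moves and no noise. Written directly from
# the codec definition, without the package's match engine, to
# cross-check play_match.
ref_table_match <- function(tab_a, tab_b, first_a, first_b, L,
                            payoffs = evaluation_payoffs()) {
  pv <- c(payoffs$R, payoffs$S, payoffs$T, payoffs$P)
  idx <- function(own, opp, t) {
    k <- min(t - 1, 2)
    rows <- (t - k):(t - 1)
    digits <- 2 * opp[rows] + own[rows]
    offset <- if (k == 2) 4 else 0
    rel <- 0
    for (d in digits) rel <- rel * 4 + d
    offset + rel + 1
  }
  a <- b <- integer(L)
  ua <- ub <- numeric(L)
  for (t in seq_len(L)) {
    a[t] <- if (t == 1) first_a else tab_a[idx(a, b, t)]
    b[t] <- if (t == 1) first_b else tab_b[idx(b, a, t)]
    ua[t] <- pv[2 * a[t] + b[t] + 1]
    ub[t] <- pv[2 * b[t] + a[t] + 1]
  }
  list(actions_a = a, actions_b = b, mean_a = mean(ua), mean_b = mean(ub))
}

# All 32 deterministic memory-one opponents: 16 response tables x 2
# forced first moves.
deterministic_memory_one <- function() {
  out <- list()
  for (tab in 0:15) {
    p <- 1 - as.integer(intToBits(tab)[1:4])
    for (fm in c("C", "D")) {
      out[[length(out) + 1]] <- reactive1_strategy(
        p, first_move = fm, name = sprintf("m1-%d-%s", tab, fm))
    }
  }
  out
}

eval_pp <- evaluation_payoffs()
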