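# mtbr

Tools for studying finite-memory strategies in iterated two-player
games — above all the repeated Prisoner's Dilemma — aimed at
researchers in evolutionary game theory and multi-agent learning who
want to benchmark strategies in pairwise contests, discover new ones by
reinforcement learning, and predict their fate in evolving populations.

The package centres on the **memory-two bilateral reciprocity (MTBR)**
strategy, a deterministic lookup table over the 20 history states of a
memory-two player, summarized by three rules:

1. forgive a lone opening defection suffered while cooperating,
2. cooperate after two consecutive rounds of mutual defection
   (break the deadlock),
3. otherwise mirror the opponent's last move.

Around it sit four pieces of machinery:

* **Match engine** (`play_match`, `expected_match_payoffs`,
  `exact_match_payoffs`): `L`-round matches with payoffs
  `R, S, T, P`, random or forced first moves, and execution noise
  `eta` (each intended action flips independently before execution).
* **Strategy zoo** (`make_mentor`, `zd_strategy`, `mtbr_strategy`,
  `table_strategy`): TFT, GTFT0.3, WSLS, Hold-a-Grudge, Fool-Me-Once,
  OmegaTFT(3,8), GradualTFT, and eight zero-determinant strategies that
  enforce `pi_opp = l + s (pi_self - l)` between long-run payoffs.
* **Multi-agent Q-learning** (`train`, `extract_policy`): tabular
  agents over the history-state codec, epsilon-greedy play against a
  mixed pool of agents and mentors, per-round reward
  `W_t = theta * U_t + (1 - theta) * Ubar_self` when weakly winning
  (else `theta * U_t`), Bellman updates
  `Q(s,a) <- Q(s,a) + alpha [W + gamma max_a' Q(s',a') - Q(s,a)]`.
* **Evolutionary dynamics** (`run_evolution`, `sweep_games`,
  `integrate_to_equilibrium`): Fermi imitation
  `p(i copies j) = 1 / (1 + exp(delta (Ubar_i - Ubar_j)))` with
  mutation on well-mixed, lattice, and Barabási–Albert populations,
  and replicator predictions
  `xdot_i = delta N / (2(N-1)) x_i (Ubar_i - Ubar)` from Monte-Carlo
  pairwise payoff matrices.

## Worked example

```r
library(mtbr)
set.seed(1)

# Two MTBR players that open on opposite moves recover immediately:
play_match(mtbr_strategy(), mtbr_strategy(),
           match_config(first_a = "C", first_b = "D"))
#> match of 20 rounds (noise 0)
#>  A: CCCCCCCCCCCCCCCCCCCC  mean 2.8500
#>  B: DCCCCCCCCCCCCCCCCCCC  mean 3.1000

# Exact self-play payoff, averaged over random first moves:
exact_match_payoffs(mtbr_strategy(), mtbr_strategy())$mean_a
#> [1] 2.9375

# Round-robin of the seven benchmark strategies plus MTBR
# (20-round PD, R=3 S=0 T=5 P=1, 10,000 matches per pair):
rr <- run_roundrobin("set1+MTBR", n_reps = 10000)
rr$per_strategy[order(-rr$per_strategy$mean_payoff),
                c("strategy", "mean_payoff")]
#>      strategy mean_payoff
#> 1  GradualTFT       2.565
#> 4     GTFT0.3       2.505
#> 8        MTBR       2.498
#> 2    OmegaTFT       2.327
#> 3         TFT       2.304
#> 6        WSLS       2.240
#> 5  FoolMeOnce       2.167
#> 7 HoldAGrudge       2.099

# Replicator dynamics over the 15-strategy roster plus MTBR,
# from a uniform start: MTBR takes over the population.
A  <- estimate_payoff_matrix(make_roster("set2+MTBR"), n_reps = 10000)
eq <- integrate_to_equilibrium(rep(1/16, 16), A, delta = 3)
round(eq$x[eq$x > 0.001], 3)
#> MTBR
#>    1
eq$mean_payoff
#> [1] 2.9375
```

The first trace shows rule 1 at work: the defector's opening move is
forgiven and both players cooperate from round 2 on, so the pair earns
close to the mutual-cooperation payoff `R = 3` (2.85 and 3.10 per
round). The self-play value 2.9375 is the exact average over the four
equiprobable first-move profiles. In the round-robin, MTBR sits just
behind GradualTFT and GTFT0.3 while raising every incumbent's average
payoff, and under replicator dynamics it drives the population to
fixation with mean payoff equal to its self-play value.

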