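# bdmvalue

Trial-by-trial **subjective reward value** from Becker-DeGroot-Marschak
(BDM) auction bids, and its encoding by midbrain **dopamine neurons** — as a
tested, end-to-end R analysis pipeline with synthetic-data generators
standing in for the behavioral sessions and electrophysiological recordings.

## The problem and who this is for

In a BDM auction the subject bids a fraction of a fixed water budget
(B = 1.2 ml) for a cued juice reward against a uniformly random computer
bid. The mechanism is second-price — winning costs the *computer's* bid —
so the expected payout

E[payout] = b·v + B − (B/2)·b²

is uniquely maximized at the truthful bid b\* = v/B: each bid reveals the
instantaneous subjective value v of the reward at that moment
(*incentive compatibility*). The scientific question the pipeline addresses:
do dopamine cue responses track this instantaneous value (the bid the animal
is about to place), or the objective reward magnitude on the screen?

The package is for computational neuroscientists and neuroeconomists who
want to (a) analyze BDM-style bidding and spike data with the exact
statistics of this paradigm, or (b) study the power and calibration of those
statistics on generators with known ground truth. It provides:

* **Auction analytics** — `resolve_auction()`, `expected_payoff()`,
  `optimal_bid()`, with incentive compatibility verified against Monte Carlo
  and grid-search oracles.
* **Synthetic behavior** — `generate_session()` / `generate_dataset()`:
  magnitude-ordered bids, a shared AR(1) latent value drift (bid coherence),
  and linear trial-history effects (starting bid, cumulative liquid,
  previous outcomes, win/lose streaks).
* **Behavioral statistics** — `rank_order_check()`, `build_design_matrix()`
  (the 31-regressor candidate set), `lasso_select()` (cross-validated,
  one-standard-error rule), `fit_mixed_model()` (three random-intercept
  forms), `bid_coherence()`.
* **Synthetic dopamine neurons** — `simulate_neuron()` /
  `simulate_population()`: 1-ms Poisson spiking with an attentional
  component and a value component driven by the bid-implied reward
  prediction error (bid × B minus the mean prediction).
* **Spike-response analysis** — `determine_window()` (data-driven value
  window from the PSTHs), `classify_neuron()` (dopamine criteria → value
  responsiveness → bid encoding), `bid_regression()`, `bin_bids()`,
  `matched_bid_comparison()` (magnitude coding at matched bids),
  `movement_control_regressions()`.
* **Pseudo-population decoding** — `assemble_pseudopopulation()` (10 bid
  deciles × 10 trials from non-simultaneously recorded neurons),
  `run_svr_cv()` (linear SVR, 5-fold 80/20 within decile),
  `decoding_curve()` (neuron-dropping curves with shuffle nulls under
  random / best-first / worst-first orderings).
* **Orchestration** — `run_pipeline()` plus plain-text CSV interchange
  (`write_session_table()`, `write_spike_table()`, `write_config()`) and a
  thin CLI wrapper at `inst/scripts/bdm-pipeline.R`.

## Worked example

```r
library(bdmvalue)

# 4 sessions of 600 trials with coherent latent value drift
dataset <- generate_dataset(subject_profile("decoding"), n_sessions = 4, seed = 7)

ro <- rank_order_check(dataset)
sprintf("pooled rho^2 = %.2f, sessions significant: %.0f%%",
        ro$pooled_rho2, 100 * ro$frac_sessions_significant)
#> pooled rho^2 = 0.79, sessions significant: 100%
bid_coherence(dataset[[1]])
#> Bid coherence (Spearman, interpolated, lower bound): L:M = 0.546  M:H = 0.602  L:H = 0.493

# 20 neurons (12 bid coders, 4 null dopamine, 4 non-dopamine), one per session slot
pop <- simulate_population(dataset, n_bid_coders = 12, n_null_dopamine = 4,
                           n_non_dopamine = 4, seed = 8)
win <- population_analysis_window(pop$recordings[pop$manifest$type == "bid_coder"])
win
#> Analysis window [ 180 , 360 ) ms
cl <- classify_population(pop$recordings, win)
sprintf("%d/%d dopamine, %d bid-encoding", sum(cl$is_dopamine), nrow(cl),
        sum(cl$is_bid_encoding))
#> 16/20 dopamine, 12 bid-encoding

# population effect size: z-scored responses vs bids, 25 bid bins
tbl <- response_table(pop$recordings[cl$is_bid_encoding], win)
binned_population_regression(tbl$z, tbl$bid)
#> Bid regression: slope 3.134, R2 0.957, p 3.16e-17 (n = 25)

# same bids, different magnitudes: no residual magnitude coding
matched_bid_comparison(tbl, c(1, 2))
#> Matched-bid 1 vs 2: 525 pairs from 9 units (3 screened out), median diff 0.000, p = 0.384

# neuron-dropping decoding curve with shuffle null
tabs <- decoding_tables(pop$recordings[cl$is_bid_encoding], win)
decoding_curve(tabs, "random", sizes = c(1, 4, 8, 12), n_iterations = 30, seed = 9)
#> Decoding curve (random ordering, accuracy = floored 1-SSE/SST)
#>   n_neurons mean_r2 shuffle_mean_r2 p_vs_shuffle
#> 1         1   0.187         0.00925     4.75e-11
#> 2         4   0.446         0.01086     2.26e-11
#> 3         8   0.590         0.00834     1.27e-11
#> 4        12   0.657         0.00671     7.88e-12
```

Reading the output: bids are rank-ordered by magnitude yet fluctuate
coherently across magnitudes (shared drift); the window algorithm recovers
the value component (180–360 ms after cue onset, excluding the attentional
component); every injected bid coder — and no null or non-dopamine cell —
passes the classification cascade; the population response rises linearly
with the bid; responses at matched bids do not differ between magnitudes
(bid coding, not magnitude coding); and decoding accuracy grows from ~19%
for one neuron toward ~66% at twelve, while shuffled labels decode at ~1%.

## Layout

```
R/                  implementation (auction, generators, analyses, decoder, pipeline)
tests/testthat/     unit, property and end-to-end validation suites
scripts/acceptance.R  headline-quantity reproduction script
inst/scripts/       bdm-pipeline.R command-line wrapper
vignettes/          methods vignette (model, parameters, numerical choices)
```
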