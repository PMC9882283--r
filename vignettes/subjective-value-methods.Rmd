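---
title: "Methods: BDM bidding, dopamine value responses, and population decoding"
author: "bdmvalue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BDM bidding, dopamine value responses, and population decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdmvalue)
```

# The scientific problem

A subject's valuation of the *same* physical reward fluctuates from moment to
moment. The Becker-DeGroot-Marschak (BDM) mechanism makes those fluctuations
observable: on every trial the subject bids a fraction of a fixed water
endowment (budget $B$ = 1.2 ml) for a cued juice reward against a computer
opponent whose bid is drawn uniformly over the bid space. The auction is
second-price: a bid $b$ that equals or exceeds the computer bid $c$ wins the
juice and pays $c$ (not $b$) out of the water budget; a losing bid keeps the
full budget. For a subjective juice value $v$ (in water-equivalent ml), the
expected payout is

$$\mathbb{E}[\text{payout}] = b\,v + B - \tfrac{B}{2} b^2,$$

which is strictly concave in $b$ and uniquely maximized at the truthful bid
$b^\ast = v/B$ — the incentive-compatibility property
(`expected_payoff()`, `optimal_bid()`; both are cross-checked in the tests
against a Monte Carlo oracle that averages realized `resolve_auction()`
payouts and against a dense grid search).

The package reconstructs, on synthetic data, the full analysis chain used to
ask whether midbrain dopamine neurons track this *instantaneous* subjective
value (the bid the animal is about to place) rather than the objective reward
magnitude on the screen: behavioral statistics, spike-response
quantification, and pseudo-population decoding.

# The synthetic behavioral generator

`generate_session()` simulates bidding with the statistical structure the
analyses assume. On trial $t$ with magnitude $m$:

$$\mathrm{bid}_t = \mathrm{clip}_{[0,1]}\!\Big(\frac{\mu_m + d_t}{B}
  + \textstyle\sum_k \beta_k x_{kt} + \varepsilon_t\Big),
  \qquad d_t = \rho\, d_{t-1} + \eta_t .$$

* $\mu_m$ — base subjective value of magnitude $m$ (water-equivalent ml),
  strictly increasing in $m$, so mean bids are rank-ordered by magnitude.
* $d_t$ — a *single* latent AR(1) value drift shared additively by all three
  magnitudes ($\rho = 0.97$, innovation SD 0.02 ml by default, stationary
  initialization). Sharing one drift is what makes bids for different
  magnitudes move coherently within a session, and the stationary draw of
  $d_1$ is what makes session means differ from day to day.
* $x_{kt}$ — centered trial-history regressors: starting cursor position,
  normalized cumulative liquid, previous same-magnitude computer bid and
  result, and same-magnitude win/lose streaks. The default coefficients are
  the per-subject mixed-model estimates for the two animals
  (`subject_profile("V")`: starting bid $-0.1$, total liquid $0.18$, win
  streak $0.016$, lose streak $-0.007$; `subject_profile("U")`: $-0.04$,
  $0.47$, $0.05$, $-0.03$).
* $\varepsilon_t$ — independent bid noise (SD 0.05 by default).

Two numerical choices deserve note:

* **Streak saturation.** The streak effect enters as
  $\min(\text{streak}, 5)$. A positive win-streak coefficient applied to
  unbounded streaks is self-reinforcing inside the closed loop (a higher bid
  wins more often, which lengthens the streak, which raises the bid), and
  bids pin to the edges of the bid space — behavior no trained animal shows.
  Raw streak counts are still recorded per trial and used as regressors.
* **Movement features** are derived deterministically from the cursor path
  over a fixed 2-s bidding epoch: velocity $=(\mathrm{bid} -
  \mathrm{start})/2\,\mathrm{s}$ and absement (mean displacement x time)
  $=(\mathrm{bid}-\mathrm{start})/2 \times 2\,\mathrm{s}$. They are therefore
  bid-correlated by construction, which is exactly the confound the
  movement-control regressions probe.

Failed (aborted) trials occur at a configurable 2% rate, deliver nothing,
leave the history state untouched, and are excluded from every analysis.

The `"decoding"` profile widens the base values to 0.2/0.6/1.0 ml and raises
the bid noise to 0.11 so that a 600-trial session populates all ten bid
deciles with at least 10 trials each — the eligibility requirement of the
pseudo-population protocol. The per-subject profiles keep the narrower,
more realistic spreads.

**What the generator does not emulate:** learning of the cue-magnitude
associations (steady state after extensive training is assumed), risk
attitude and utility curvature (deliberately minimized by the 3-magnitude
design), satiety-induced *systematic* late-session devaluation beyond the
linear liquid term, and any oculomotor or licking behavior. Passing tests on
this generator therefore demonstrate that the *analysis chain* recovers what
was injected — not that real monkeys behave this way.

# The synthetic dopamine neurons

`simulate_neuron()` draws 1-ms-binned inhomogeneous-Poisson spike trains
around two alignment events (magnitude-cue onset and the computer-bid /
water-payout cue). The cue response has the canonical two components:

1. an **attentional** boxcar (default +15 Hz over 100-180 ms) identical
   across magnitudes and bids, and
2. a **value** boxcar (default 180-360 ms) scaled by the trial's reward
   prediction error
   $$\mathrm{pe}_t = \mathrm{bid}_t \times B - \bar\mu,$$
   the bid-implied subjective value minus the mean of the three base values
   — i.e. the prediction standing at the trial-start cross before the
   magnitude cue appears. The ground truth of bid-coding neurons is the
   *bid*, not the magnitude, which is precisely what the analyses must
   recover. An optional `magnitude_gain_hz` adds direct magnitude coding for
   testing the matched-bid analysis.

Two realism constraints shape the value component:

* **Rate floor.** Rates are floored at 0 Hz, so negative prediction errors
  express as bounded depressions.
* **Asymmetric prediction-error coding** (`neg_scale = 0.4`): suppression to
  negative PEs is weaker than excitation to positive PEs, as the low
  baseline rate of dopamine neurons leaves little dynamic range below
  baseline. Beyond realism this matters statistically: with a perfectly
  linear Poisson code, bin-averaged population responses are almost exactly
  linear in the bid (bin means pool hundreds of trials), and the 25-bin
  population regression $R^2$ saturates near 1 for any usable gain. The
  asymmetry bends the population bid-response curve and caps that $R^2$
  around 0.94 independent of gain, which is what makes an effect-size
  calibration against the population regression meaningful at all.

Default parameters: baseline 6 Hz and waveform width 2.5 ms (inside the
dopamine criteria of < 10 Hz and > 1.8 ms), value gain 12 Hz per ml of
prediction error — about +6 Hz at the largest positive PE, a physiologically
modest phasic modulation. `simulate_population()` distributes neurons one
per session over a multi-session dataset (non-simultaneous recording),
jitters bid-coders' gains uniformly by +/-50%, and records all ground-truth
gains in a manifest. Non-dopamine neurons get narrow waveforms (0.8 ms),
high baselines (25 Hz) and no value component.

**Gain calibration.** `calibrate_value_gain()` constrains the value gain so
that the pooled z-normalized population response, averaged within 25 bid
bins and regressed on the bids, lands in a target $R^2$ band (default
[0.85, 0.95], the range the recorded populations show). The calibration is
constraint satisfaction, not optimization: it starts at the configured
default gain and verifies the band, stepping along a grid only when out of
band (the population $R^2$ is monotone in the gain up to its
asymmetry-limited plateau). Because the feasible set is a wide interval of
gains, "the smallest gain in the band" would merely select the band's noisy
entry flank; verifying the physiologically chosen default is the more
stable and more honest rule.

# Spike-response analysis

All scalar statistics are computed from **unsmoothed** 1-ms counts; the
80/100-ms moving averages exist only for displayed traces (`psth()`).

**Baseline and z-normalization.** The baseline epoch is 0-500 ms before the
trial-start cross (raster times $-1000$ to $-501$ ms relative to cue onset).
Group-level analyses use $z = (r - \bar r_{\mathrm{base}}) /
\mathrm{sd}(r_{\mathrm{base}})$ per neuron, so no neuron dominates by firing
rate; a zero baseline SD excludes the neuron with a flag.

**Analysis-window detection** (`determine_window()`). The value window must
exclude the attentional component. Its start is where the lowest-magnitude
averaged response (which carries a *negative* PE and therefore cannot
prolong the positive attentional deflection) first returns to the baseline
mean after the initial peak; its end is the trailing edge of the last 20-ms
bin in 0-500 ms where the highest-magnitude response still differs from
baseline (Wilcoxon sign-rank across trials, Bonferroni-Holm over the 25
bins). Two numerical choices:

* The start crossing is detected on the **20-ms-binned** averaged trace
  (first bin at/after the peak bin whose mean falls to or below the baseline
  mean; the window starts at that bin's leading edge — the 20-ms rounding of
  the crossing). A 1-ms crossing rule is unusable on trial-averaged Poisson
  traces: at 5-6 Hz and 300 trials a single 1-ms bin of the average has
  roughly 4 Hz of sampling noise, so the raw trace crosses baseline
  constantly. On noise-free boxcar traces the binned rule reproduces the
  1-ms rule exactly.
* The end-of-window sign-rank compares each trial's 20-ms window count with
  a **duration-matched** 20-ms bin of that trial's baseline epoch. The
  difference of two equal-rate Poisson counts is symmetric (Skellam), so the
  sign-rank null is valid even at low rates; comparing counts of unequal
  durations would make the null asymmetric and inflate false positives.

On noise-free traces the algorithm recovers boxcar edges exactly; under
Poisson noise at 300 trials it stays within one 20-ms bin of the true edges
in well over 90% of simulations (tested).

**Classification cascade** (`classify_neuron()`): putative dopamine = wide
waveform (> 1.8 ms) AND low baseline (< 10 Hz) AND a significant 0-200 ms
response to at least one task event (sign-rank against a duration-matched
baseline segment); value-responsive = significant single regression of the
windowed response on magnitude rank for either cue (magnitude *rank* is used
as the regressor; ml volume would only rescale the test); bid-encoding =
significant simple regression of the windowed cue response on the bids,
evaluated only among dopamine neurons. The bid-encoding test is two-sided at
$\alpha = 0.05$ with the slope recorded, so its false-positive rate is the
nominal 5% on null neurons (verified on 500 simulated null cells);
positive-slope subsets can be taken from the recorded slope.

**Bid binning.** Tenths and quintiles are fixed equal-width partitions of
the bid space (right-closed, a bid of exactly 0.1 falls in the first tenth).
The skew-corrected terciles assign equal *counts* by bid rank with ties
split in order of occurrence — with 8 identical low bids among 10 trials the
three bins hold 4/3/3 trials.

**Matched-bid magnitude test** (`matched_bid_comparison()`). Within each
neuron's session, trials of two magnitude levels are paired greedily in
ascending bid order (nearest available partner within 5% of the bid space,
each trial used once — deterministic and reproducible); units whose matched
bid distributions still differ (rank-sum p < 0.05) are screened out; pooled
response differences (higher minus lower magnitude) are tested for zero
median with a sign-rank test. The three magnitude pairs are tested at
per-comparison $\alpha = 0.05$ without a multiplicity correction, matching
the original protocol; the output reports all three p-values so readers can
apply their own correction. Under pure bid coding the test is calibrated
(~5% false positives); a magnitude effect of one baseline SD is detected
with power above 80% at 300-trial sessions and 8 neurons (tested).

# Pseudo-population decoding

`assemble_pseudopopulation()` joins non-simultaneously recorded neurons on
the shared bid-decile label: bids are discretized into 10 right-closed
deciles; every eligible neuron (>= 10 trials in *each* decile) contributes
10 randomly selected trials per decile, giving 100 pseudo-trials; the i-th
sampled trial of each neuron within a decile forms pseudo-trial i. The
regression target of a pseudo-trial is the actual bid contributed by a
randomly designated anchor neuron for that decile — keeping the target
continuous rather than a bin midpoint.

`run_svr_cv()` fits a linear support-vector regression
(via e1071, cost 1, epsilon 0.1, responses standardized by training-fold
statistics) under five-fold cross-validation that partitions trials within
decile: every fold trains on exactly 8 and tests on exactly 2 trials per
decile (80%/20%). Reported accuracy is the held-out explained variance
$\max(0,\, 1 - \mathrm{SSE}/\mathrm{SST})$, floored at zero per fold.
The floored explained-variance form (rather than squared Pearson
correlation) is deliberate: squared correlation is never negative and
carries a positive small-sample bias of roughly $1/(n-1)$ (~5% on 20 test
trials), so only the explained-variance form can report chance-level
decoding as 0%. Squared correlation remains available via
`r2_method = "cor"`.

`decoding_curve()` repeats assembly and cross-validation over fresh random
trial selections (300 iterations by default; 50 in the test suite) for each
population size under an ordering policy — random (fresh order per
iteration), best-first, or worst-first by each neuron's simple-regression
$R^2$ with the bids — and computes an identical shuffle null by permuting
the bid targets across all pseudo-trials within each iteration
(across-decile permutation, which destroys all bid information). Real and
shuffled iteration-level accuracies are compared by rank-sum test at
$\alpha = 0.01$. The full curve is byte-reproducible from its seed.

# Problem sizes and runtime choices

The test suite and the reproduction script use 600-trial sessions, 20-30
neuron populations, 50-300 decoding iterations, 100-seed property checks
for window recovery and coherence, 500 simulated neurons for the
false-positive calibration, and 50 simulated datasets for mixed-model sign
recovery. These sizes keep every run on a laptop-scale machine while leaving
the Monte Carlo error well below the margins being tested.

# Known limitations

* The generator's bid-response relation is piecewise linear by construction;
  analyses that would probe finer nonlinearities (utility curvature,
  reference dependence) have no ground truth here and are out of scope.
* The coherence estimate interpolates bids across trials where a magnitude
  was absent and is therefore a lower bound; the package makes no attempt to
  deconvolve the attenuation.
* Mixed-model p-values use the large-sample normal approximation;
  small-sample degrees-of-freedom corrections are not implemented.
* The decoder uses a single linear kernel with fixed hyperparameters;
  nonlinear kernels and binary classifiers are out of scope.
* Day-of-week and session-number regressors exist in the design matrix but
  carry no injected structure beyond session identity, so their selection
  frequency under the lasso is not a meaningful recovery test.
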