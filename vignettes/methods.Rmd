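---
title: "From resting-state phase locking to task prediction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From resting-state phase locking to task prediction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plvnet)
```

## The scientific question

Can the brain's intrinsic functional organization — measured while a
person does nothing in particular — predict how well that person will
later adapt their motor behavior to covert temporal regularities in a
task? `plvnet` implements the analysis chain that addresses this
question with source-projected, parcellated resting-state EEG:

1. **Connectivity.** Band-limited phase-locking values (PLV) between
   all parcel pairs give a symmetric adjacency matrix per subject and
   frequency band.
2. **Prediction.** The edge weights of a named sub-network are features
   in a leave-one-subject-out (LOSO) linear support-vector regression
   that predicts a scalar behavioral or ERP index; accuracy is the
   Bayesian correlation between concatenated observed and predicted
   values, reported only when the Bayes factor clears `sqrt(10)`.
3. **Nodal characterization.** Each subject's network is proportionally
   thresholded at a retention level chosen to preserve small-world
   topology, normalized, and summarized per node by degree, strength,
   weighted clustering and local efficiency; these nodal metrics are
   then correlated with the same indexes.

Because real recordings of this kind are large and subject to consent
restrictions, the package also ships seeded generators that emulate the
three kinds of input the pipeline needs. Every stage is therefore
testable end-to-end on a laptop, with known ground truth.

## Phase-locking value

For two signals with instantaneous phases $\phi_a(t)$ and $\phi_b(t)$,
the per-epoch PLV is the mean resultant length of the phase difference,

$$\mathrm{PLV}_{ab} \;=\; \Bigl|\tfrac{1}{T}\sum_{t=1}^{T}
  e^{i(\phi_a(t)-\phi_b(t))}\Bigr| \in [0,1],$$

averaged across epochs. Phases come from the analytic signal (Hilbert
transform) of band-limited epochs. Choices the definition leaves open,
and what this package does:

* **Filter.** A zero-phase windowed-sinc FIR band-pass (Hamming
  window) applied per epoch with reflective padding, forward and
  backward. Zero phase matters: any phase distortion would bias the
  statistic being measured. The order scales as `6.6 * fs / low`
  (capped at the epoch length minus one) so that one octave below the
  band's low edge is well inside the stop band; the shipped tests
  verify pass-band unity gain within 5% and stop-band leakage below 5%.
* **Edge trimming.** 10% of samples at each epoch edge are discarded
  before averaging (configurable via `edge_trim`), suppressing filter
  and Hilbert edge transients.
* **Diagonal.** Stored as 0 and excluded from all downstream features.
* **Canonical bands.** Delta 2–4, theta 4–7, alpha 8–12, beta 13–30,
  gamma 30–45 Hz (`canonical_bands()`).

A caveat worth stating explicitly: band-limited signals have phase
autocorrelation on the order of the inverse bandwidth, so the PLV of
two *independent* band-limited signals sits well above the
i.i.d.-uniform chance level $\sqrt{\pi}/(2\sqrt{T})$. This is the
well-known PLV sample bias. The package's null checks therefore test
the statistic itself (`phase_locking_value()`) against uniform phase
streams, and test generator output through the *ordering* of coupling
strengths rather than an absolute chance floor.

## The synthetic generators

**Coupled oscillatory epochs** (`simulate_coupled_epochs()`). Each
region carries, per requested band, a phase-diffusing sinusoid: linear
phase at the band's center frequency plus a Gaussian random walk
(default innovation 0.25 rad/sample) and a random start phase per
epoch. For a coupling edge $(i, j)$ with strength $s$ and lag
$\theta$, region $j$'s band component is
$s\cos(\phi_i - \theta) + (1-s)\cos(\phi_j)$ with $\phi_j$
independent. This is the simplest model in which expected PLV grows
monotonically from chance level ($s = 0$) to exactly 1 ($s = 1$, no
noise, constant lag), which the suite verifies. Defaults mirror a
typical resting recording: 2-s epochs, 60 epochs (two minutes). The
generator makes no attempt to match empirical 1/f spectra, amplitude
dynamics, or volume conduction; passing tests say the *pipeline*
behaves correctly, not that the signals are physiologically realistic.

**Cohort connectivity with planted effects**
(`simulate_cohort_connectivity()`). Per subject, each edge gets an
independent latent standard normal score, squashed through the
logistic function into $(0,1)$. A target index is
$\sum_e \beta_e\, z(\text{edge}_e)$ plus Gaussian noise, where
$z(\cdot)$ is z-scoring across the cohort — so with one planted edge
of $\beta = 1$ and noise sd $\sigma$, the population edge–target
correlation is $1/\sqrt{1+\sigma^2}$, and with $\sigma = 0$ the
recovery problem has an exact answer. Cohort sizes default to 46
(behavioral) and 40 (neural), the sizes at which the Bayes-factor
accuracy gate is calibrated. The optional `"small_world"` backbone
shifts latent edge means up along a ring lattice and down elsewhere,
giving thresholded graphs the clustered, short-path topology of
cortical networks; the pipeline's synthetic cohorts use it, because
threshold selection by the small-world criterion is only meaningful on
graphs that can be small-world at all. Exchangeable-edge cohorts
(`backbone = "none"`) remain the null model for calibration tests.

**Task schedules and behavior** (`simulate_dtp_behavior()`). The
variable-foreperiod design: warning stimulus, then an imperative
stimulus after a short (500 ms), medium (1000 ms) or long (1500 ms)
SOA. Block types bias the SOA distribution — fast 50/33.33/16.67%,
uniform flat, slow the reverse — with 60 trials per block, each type
delivered three times: 540 trials, SOA counts 90/60/30 in fast and
30/60/90 in slow blocks, block order randomized per subject. RTs are
linear in SOA rank (motor preparation grows with elapsed foreperiod)
with a block-type shift of $\pm g/2$ so the fast-minus-slow
("delta global") RT difference recovers the adaptation gain $g$
exactly when noise is off; premature responses are Bernoulli with
block-type-specific rates and get RTs below 150 ms.

## Behavioral indexes

Only non-premature responses with RT in the closed interval
[150, 1500] ms count as correct and enter RT means (the design's
stated window; we read "between" as inclusive, which only matters for
RTs landing exactly on a bound). Accuracy is the proportion of
non-premature responses; omissions count against accuracy but not
against the premature-error proportion PE. The inverse efficiency
score IES = RT/(1 − PE) corrects mean RT for the speed–accuracy
trade-off. Every delta-global index is the fast-block minus slow-block
difference; uniform blocks are simulated and summarized but never
enter these indexes.

## Bayesian correlation

Inference about a Pearson correlation uses the Jeffreys-lineage
reduced likelihood, in which the data enter only through $(r, n)$:

$$L(\rho \mid r, n) \propto (1-\rho^2)^{(n-1)/2}(1-\rho r)^{(3-2n)/2}
  \,{}_2F_1\!\left(\tfrac12,\tfrac12; n-\tfrac12;
  \tfrac{1+\rho r}{2}\right),$$

with a stretched beta prior on $(-1,1)$: $(\rho+1)/2 \sim
\mathrm{Beta}(1/\kappa, 1/\kappa)$, width $\kappa = 0.5$ by default.
BF10 is the prior-averaged likelihood over the likelihood at
$\rho = 0$, by adaptive quadrature (relative tolerance $10^{-8}$); the
${}_2F_1$ series always converges here because its third parameter
grows with $n$. One-sided tests truncate and renormalize the prior to
a half-line. Credible intervals are central posterior quantiles
computed on a 4001-point grid. The suite checks the implementation
against an independent fixed-grid trapezoid oracle, its symmetries
(two-sided BF even in $r$; positive-side BF at $r$ equals
negative-side at $-r$), and monotonicity in $n$.

```{r bf-example}
bayes_cor_test(0.31, 46, kappa = 0.5, side = "positive")
```

Reporting is gated at BF10 > $\sqrt{10} \approx 3.162$ (strictly), and
prediction accuracies additionally require $r > 0$: a negative
observed-vs-predicted correlation means a failed fit, not evidence of
"anti-prediction". `bf_robustness()` recomputes BF10 over a grid of
prior widths, the standard check that a conclusion does not hinge on
$\kappa$. Sidedness for prediction accuracy is always one-sided
positive; for nodal-metric correlations the package defaults to
two-sided (either sign is interpretable there) with a configuration
switch, since both conventions are defensible.

One consequence of the $(r, n)$ sufficiency is worth knowing: Bayes
factors are extremely sensitive to the third decimal of $r$ when the
evidence is strong, so BFs computed from a rounded, printed $r$ can
differ noticeably from BFs computed from the underlying data. This is
a property of the statistic, not a numerical artifact; the quadrature
itself is stable to better than 0.1%.

## LOSO prediction

Features are the strictly-below-diagonal entries of each subject's
network-restricted PLV matrix, in fixed row-major order
($m(m-1)/2$ features for an $m$-node network). For each held-out
subject, target and features are z-scored **on the training fold
only**, a linear $\varepsilon$-insensitive SVR is fitted (box
constraint $\mathrm{iqr}(y)/1.349$, tube $\mathrm{iqr}(y)/13.49$ on
the standardized target — robust-scale defaults exposed in
`svr_config()`), and the held-out subject is predicted from its
training-scaled features, mapped back to raw units. A
`leakage_compat` switch standardizes on the full cohort instead, to
mimic pipelines that z-score once before splitting; in our
experiments the two differ negligibly at these cohort sizes. The
no-leakage property is asserted bit-exactly in the tests: corrupting a
held-out subject's target never changes its prediction.

Two calibration facts shape expectations for this design. First, the
LOSO observed-vs-predicted correlation *attenuates* the planted
effect: with a single informative edge at population edge–target
correlation 0.6 ($n = 46$, 4-node network), the accuracy distribution
centers near $r \approx 0.45$ with sd $\approx 0.15$ — the extra
uninformative edges and fold-wise refitting both cost signal, and the
cost grows quickly with network size (mean $r \approx 0.29$ at 8
nodes). We verified the same attenuation with an independent SVR
implementation, so it is intrinsic to the estimator, not to this code.
Second, the gate is conservative under the null: across 100
pure-noise cohorts at $n = 46$, the one-sided gate opens in about 6%
of runs. Validation scenarios in the suite therefore use 4–5-node
networks, the regime where a single planted edge is recoverable.

## Graph analysis

**Thresholding.** `proportional_threshold()` keeps exactly the top
$\lceil p \cdot E \rceil$ off-diagonal weights, unbinarized. Ties at
the cut break by $(i, j)$ lexicographic order, which makes retained
edge sets nested across $p$ — asserted as a property test.
**Normalization.** Weights are divided by the maximum retained weight
(so strength is bounded by degree), because the weighted metrics
depend on the scale of the mean connection weight.

**Nodal metrics** on the normalized graph: degree (incident retained
edges), strength (incident weight sum), weighted clustering in the
geometric-mean-of-triangle-weights form
$C_v = \frac{1}{k_v(k_v-1)}\sum_{j \ne h}
(w_{vj} w_{vh} w_{jh})^{1/3}$, and local efficiency as the mean
inverse weighted shortest-path length (edge length $1/w$) between
$v$'s neighbors in the subgraph excluding $v$. Isolated and degree-1
nodes get clustering and local efficiency 0 by convention. All four
metrics are checked to $10^{-9}$ against a brute-force oracle
(explicit triangle enumeration and Floyd–Warshall) on 50 seeded random
5–6-node graphs.

**Small-worldness.** $\sigma = (C/C_{\mathrm{rand}})/
(L/L_{\mathrm{rand}})$, where $C$ is mean weighted clustering, $L$ the
mean finite weighted shortest-path length, and the null statistics are
averaged over degree-preserving double-edge-swap rewirings (default 20
nulls, 10 swap attempts per edge, seeded) that carry edge weights with
the rewired edges — preserving the degree sequence and the weight
multiset exactly, both asserted per rewire in the tests. The weighted
(not binarized) reading is used throughout, matching unbinarized graph
construction. On a complete graph every swap is rejected, so
$\gamma = \lambda = \sigma = 1$ exactly — a useful anchor case. A
graph whose nulls contain no triangles has no meaningful $\sigma$;
`small_world()` flags this as degenerate.

**Threshold selection.** For each candidate $p$, $\sigma$ is computed
per subject; the selected $p^\ast$ is the **largest** $p$ whose
cohort-mean $\sigma$ exceeds 1. "Largest" (densest) is the reading
consistent with the rule's purpose — discarding the fragmented graphs
that arise at low retention. Retention levels where a subject's graph
is degenerate simply fail to qualify rather than aborting the scan; if
no level qualifies, selection errors and prints the $\sigma$-vs-$p$
table. `select_threshold()` accepts an injectable small-world engine
so the selection rule itself can be unit-tested against a constructed
$\sigma$ profile, separately from the Monte-Carlo engine.

## The pipeline and problem sizes

`run_pipeline()` chains the stages: per-band synthetic cohorts
(behavioral and neural separately), LOSO prediction for every band ×
network × target, threshold selection and nodal metrics on the
intersection network (response-implementation regions that also belong
to either expectancy network), and gated nodal-metric correlations
with robustness summaries for the gated rows only. Outputs are
deterministic JSON/CSV plus a manifest with the package version, seed
and config hash; reruns with the same seed are byte-identical, which
the suite asserts. The only multiple-comparison control is the
$\sqrt{10}$ gate itself, mirrored from the analysis the package
implements; the manifest records how many tests were run so a reader
can judge the multiplicity.

The shipped tests exercise the full pipeline at reduced scale — two
bands, 10 regions, cohorts of 8–10, 3 nulls — sizes chosen so the
complete suite runs in a few minutes while still covering every code
path; the statistical calibration tests use the full cohort sizes
(46/40) where the gate's behavior actually depends on $n$. The
shipped network label files are illustrative placeholders: real
analyses supply their own region sets.

## Known limitations

* The oscillator model is phenomenological: no 1/f background, no
  amplitude–phase coupling, no volume conduction or leakage between
  parcels. PLV estimates on real source-projected EEG carry biases
  (notably from residual leakage) that the synthetic data do not show.
* Linear SVR only; no nonlinear kernels or nested hyperparameter
  tuning. The LOSO accuracy attenuates planted effects (quantified
  above), so observed $r$ should be read as a lower bound on the
  underlying association strength.
* Credible intervals come from a fixed-grid posterior CDF; they are
  accurate to well under 0.01 at the package's grid size but are not
  sampling-based posterior summaries.
* Disconnected node pairs are excluded from characteristic path
  length; the small-world-controlled threshold choice is designed to
  avoid the fragmented regime where that exclusion would matter.
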