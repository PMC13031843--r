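---
title: "Methods: multi-region short-term-memory analyses in cortexcomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region short-term-memory analyses in cortexcomm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cortexcomm` is an analysis toolkit for trial-structured, multi-region
population recordings from a whisker-based delayed-response task: a 1-s
tactile stimulus on the left or right whiskers, a 4-s delay during which
brief bilateral distractors may be delivered (1, 2 or 3 s after delay
onset, each on ~10% of trials), and a 4-s response epoch cued by a tone.
Eight dorsal-cortex regions (ALM, M1a, M1p, M2, S1fl, vS1, RSC, PPC) are
imaged simultaneously at ~9.35 Hz; activity is z-scored deconvolved event
amplitudes. The package provides:

* single-neuron epoch and trial-type selectivity, and distractor-mediated
  modulation of selectivity;
* three functional-interaction metrics (inter-trial-interval pairwise
  correlation, trial-by-trial correlation, cross-validated ridge
  population prediction) and their consistency;
* reduced-rank-regression communication subspaces, principal-angle
  subspace similarity, spatial and temporal degeneracy, and ablation of
  predictive dimensions;
* a FORCE-trained recurrent-network simulator of delay-period attractor
  dynamics, with distractor perturbation and connectivity-ablation
  experiments;
* a pseudo-mouse population-decoding pipeline with a pluggable 3-d
  embedding backend and kNN readout;
* one-tailed bootstrap group comparisons and Benjamini-Hochberg FDR;
* a seeded synthetic-cohort generator with a "control" and a
  "reduced-connectivity" preset, standing in for the two imaged cohorts.

All analyses run on the `cortex_session` container (activity matrix,
region labels, frame rate, trial table). Epoch arithmetic uses 0-based,
half-open frame intervals with `frame = floor(t_seconds * rate) + onset`;
the epochs are stimulus [0,1) s, delay [1,5) s, action [5,9) s, the
inter-trial window [−5,−1) s and the trial window [−1,7) s relative to
stimulus onset. The response-epoch end is taken at +9 s; nothing in the
package depends on activity after that point.

# The synthetic cohort generator

The generator (`generator_config()`, `generate_cohort()`) is a stated
world, not a curve fit: its defaults encode the task design (180 trials
per session, ~10% of trials per distractor condition, inter-trial
intervals drawn uniformly from {6, 7, 8} s) and a latent-factor population
model chosen once to look like calcium population data:

* Per region, paired **side-specific task latents** (choice R/L ramping
  linearly over the delay and held through the action epoch; stimulus R/L
  active during the stimulus epoch; action R/L active during the response
  epoch) plus background AR(1) latents of unit stationary variance
  (lag-one coefficient 0.8). Regional amplitude profiles place stimulus
  latents strongest in vS1/S1fl, choice latents strongest in ALM/M2/PPC
  and action latents strongest in ALM/M1.
* Neurons mix latents through **nonnegative loadings** (each neuron has a
  "home" background latent; a configurable fraction per region
  additionally loads one side of one task-latent pair, making it
  epoch-selective) plus private Gaussian noise (SD 1), and are z-scored.
* **Inter-regional transmission** is low-rank and lagged by one frame:
  each ordered region pair has a rank-3 map built from sparse nonnegative
  source channels with decaying gains (1, 0.8, 0.64) and target mixing
  onto background latents, plus a side-consistent choice passthrough
  (gain 0.5). Nonnegative channels make transmitted activity correlate
  positively with target loadings, as empirical inter-areal correlations
  do; the decaying spectrum keeps "the first m predictive dimensions"
  well-defined. The fraction of source-channel structure shared across
  different targets of the same source is the **spatial-degeneracy knob**
  (`channel_overlap`, default 0.9).
* **Distractors** add a 0.2-s pulse to the sensory-region stimulus
  latents; a `distractor_susceptibility` gain leaks the pulse into the
  opposite-side choice latents with a 1.5-s exponential tail, degrading
  both end-of-delay behavior and decodability.
* **Behavior** is a logistic readout of the mean choice-latent difference
  over the last 0.5 s of the delay (slope 3), with a 3% no-response rate.
  The only contract is directional: higher susceptibility lowers
  distractor-trial performance.
* The **reduced-connectivity preset** scales all coupling gains by 0.4,
  lowers `channel_overlap` to 0.15 and raises susceptibility to 1.0.

What a green test does and does not establish: the generator reproduces
the *structure* the analyses assume (epoch-locked selectivity, positive
and low-rank inter-areal coupling, distractor leakage) but not the
statistics of real calcium data — no sparse/nonnegative event statistics,
no slow drift, no behavioral state changes, no cell-count imbalance
across regions, and trial-averaged delay selectivity differs between the
presets (in the modeled mice, baseline selectivity was comparable and
only distractor robustness differed). Direction checks on synthetic
cohorts validate the machinery, not the biology.

Deterministic distractor allocation (`distractor_allocation = "exact"`)
exists for tests; multinomial sampling is the realistic default. The same
`(config, seed)` yields bit-identical cohorts.

# Selectivity

A neuron is epoch-selective if its per-trial mean activity differs
between correct left and correct right trials (two-tailed Wilcoxon
rank-sum, p < 0.01); regions with fewer than 10 recorded neurons are
excluded. Trial-type selectivity profiles subtract left-trial from
right-trial mean activity per delay-selective neuron over the trial
window, so right-preferring neurons deflect upward; the population
selectivity trace is the difference between the two preference groups,
all smoothed with an identical centered boxcar of `round(0.5 s × rate)`
frames (forced odd, half-sample-symmetric reflection — this makes the
smoother exactly mean-preserving). If one preference group is absent its
trace is zero (it deflects nowhere), rather than undefined.

Distractor-mediated modulation combines correct and incorrect trials,
averages the selectivity trace over a 1-s window anchored at the
distractor **offset** (onset + 0.2 s; onset anchoring is available via
`anchor = "onset"`), and subtracts the same quantity computed from
non-distractor trials.

# Functional-interaction metrics

* ITI functional connectivity: pairwise Pearson correlation of
  concatenated inter-trial-interval activity (−5 to −1 s), averaged over
  neuron pairs within each region pair, then across sessions
  (unweighted — weighting by pair count was considered and rejected for
  simplicity; cells with fewer than 10 pairs are dropped).
* Trial-by-trial correlation: the same on the −1 to +7 s trial window.
* Population prediction: ridge regression (closed form,
  `(X'X + λI)^{-1} X'Y`) from 10 sampled source neurons to 10 sampled
  target neurons, λ on a 10-point log grid from 1e−3 to 1e3 chosen by
  10-fold cross-validation on contiguous blocks; performance is
  `1 − cvl`, where `cvl` is the mean across folds of per-target
  `SSE/SS_total`, averaged over targets. 20 sampling repeats are
  averaged. The intra-regional case samples disjoint source/target sets
  and needs ≥ 20 neurons.

Activity matching across cohorts (`subsample_matched()`) retains neurons
above a preset threshold (default: pooled-cohort median of per-neuron
mean activity — the study states no value) and then greedily pairs
neurons one-to-one across cohorts on mean activity with a caliper of
0.05 pooled SD, which guarantees the post-subsampling cohort means agree
to well under 0.1 pooled SD; regions that cannot reach the minimum
matched count are dropped.

# Communication subspaces

Reduced-rank regression limits the rank of the ridge solution:
`B_rrr = B_ridge V V'`, with `V` the top-m right-singular vectors of the
ridge-predicted targets `Ŷ = X B_ridge`. The description of `V` in the
source methods ("SVD of the covariance matrix of X and Y") is ambiguous;
the predicted-target convention of the reference communication-subspace
implementation is the default and the cross-covariance reading is
available via `v_from = "cross"`. The predictive dimensions are the
columns of `B_bar = B_ridge V`. The optimal rank is the smallest rank
whose 10-fold cross-validated performance is within one SEM (across
folds, at the peak) of the peak.

Subspace similarity orthonormalizes both bases by QR and reports the
cosine of the **largest** principal angle (the smallest singular value of
`Qa' Qb`), matching the reference routine's semantics; the smallest-angle
variant is available. Spatial degeneracy compares the first three
predictive dimensions of one source toward two targets; temporal
degeneracy compares per-window fits over the seven 1-s windows (ITI,
stimulus, delay 1–4, action), single fits per window (no per-window
cross-validation).

Ablation of predictive dimensions removes the source components
correlated with the first m predictive dimensions: `M = B_bar' Σ` with
`Σ` the source covariance, `Q` the last p−m right-singular vectors of
`M` (so `MQ = 0`), and `X̂ = XQ`; downstream ridge predictions are re-fit
on `X̂` and reported normalized by the matched unablated performance.
With m = 0, `Q` is a full orthonormal basis and ridge performance is
unchanged (the isotropic penalty is rotation-invariant).

# The FORCE-trained recurrent network

The rate network `τ ẋ = −x + J r + W_stim I_stim + W_cue I_cue + ε`,
`r = σ(β (x − θ))`, is integrated by Euler steps (τ = 10 ms, dt = 1 ms,
β = 1, θ = 3, per-step noise SD 0.15). `J` is initialized N(0, g/√n)
with g = 1.2, `W_stim` N(0, 1), `W_cue` N(0, 0.1); all dispersion
parameters are read as standard deviations (a variance reading is one
flag away). Training follows the first-order reduced and controlled
error recursive-least-squares rule per timestep, alternating right/left
episodes, with `P` initialized once to `α I` (α = 0.005, the literal
printed reading; the classical `I/α` is available) and learning rate 0.05.
The 5.5-s trial span runs from 0.5 s before stimulus onset to the delay
offset: stimulus is a triangular pulse over span seconds [0.5, 1.5)
(peak N(1, 0.1) on right trials, exactly 0 on left trials), the go-cue
pulse occupies [1.4, 1.5) with peak 1, and the optional 500-ms distractor
occupies [3.2, 3.7) with peak N(2.5, 0.25), entering through the stimulus
pathway. Episode initial currents are the mean of the two target sets'
first samples; the membrane current is recoverable from activity by the
inverse sigmoid.

Target construction from trial-averaged activity excludes units never
reaching 1 SD, clips to [0.01, 4.99] (the ±0.01 "slight offsets" applied
to the 0 and 5 clip bounds, guaranteeing interior values), normalizes by
5, samples n units with replacement, applies the inverse sigmoid,
up-samples tenfold by linear interpolation and smooths with a 400-ms
boxcar.

**Why the bundled training targets come from a reference network.** A
per-timestep recursive-least-squares fit of target *currents* only
converges to dynamics the architecture can actually stabilize. Targets
that sit at a quiescent fixed point and then depart at a scheduled time
without any input are dynamically infeasible (the flow cannot encode the
schedule), and even exact teacher-forced least-squares solutions of such
targets free-run unstably. The bundled fixture therefore generates its
two-trial-type targets by simulating a hand-built bistable
winner-take-all network (self-excitation 6, cross-inhibition −1.5 between
two pools around a sigmoid threshold of 3, a heterogeneous decay pool,
and an initial state committed to the "left" attractor): a quiet/left
attractor reached autonomously, a right attractor reached through the
stimulus pulse, and trajectories that are stable by construction. On
these targets the literal printed constants converge cleanly (final/first
epoch MSE ≈ 0.04–0.09 at 300 epochs on 64 units; noiseless output-target
correlation ≥ 0.97 per trial type across seeds).

**Operating point of perturbation experiments.** The 64-unit fixture
network switches decisions at distractor amplitudes near 0.5; the
full-scale amplitude 2.5 is deep in its always-switch regime, where
weight ablation *reduces* switching by degrading the destination
attractor. The distractor-amplitude robustness check therefore uses the
stated amplitudes {0, 1.25, 2.5, 5} (monotone by saturation), while
ablation experiments probe near threshold (amplitude 0.3, random subset
fraction 0.25) — the regime with below-ceiling baseline switching in
which ablation destabilizes the holding attractor. Decision switching is
read out as the mean of the final 10 ms of the choice-axis projection
lying strictly above the midpoint of the two non-distractor references;
an exact midpoint does not count as a switch.

The choice axis is the l2-normalized difference of trial-averaged
activity between right and left trials in the pre-action window (last
1 s of the delay; 0.5-s and 1.5-s variants supported); projections are
baseline-subtracted (0.5-s ITI window, per condition) and normalized by
the maximum right-trial choice activity.

**Cohort contrast at desk scale.** Directly fitting the synthetic
sessions' z-scored trial averages is subject to the same stability
obstruction, so the cohort-contrast experiment propagates the cohort
signal by measurement instead: `cohort_separation()` computes each
cohort's late-delay trial-type separation from its generated sessions,
and `separation_to_depth()` (an affine map calibrated once so the control
cohort's typical separation ≈ 0.6 z-units gives full depth, clamped to
[0.4, 1]) scales the reference-target attractor depth. Weaker coupling
measurably weakens separation, which yields shallower attractors and
more post-ablation switching — the full causal chain runs through
generated data at run time.

# Pseudo-mouse decoding

Region pools stack cells across sessions over delay-period frames,
sampling matched trial counts per session (40 per side from
non-distractor trials and 4 per side per distractor condition in choice
mode, per the source protocol; the same scheme is used in stimulus mode
so pseudo-trials align across sessions — the full-data stimulus protocol
uses all trials, which cannot align across synthetic sessions of
different lengths). Sessions with too few trials are excluded. A
pseudo-mouse samples a fixed number of cells per region (200 in
stimulus/unsupervised mode, 1600 rows; 145 in choice mode, 1160 rows).

The embedding backend contract is `fit(activity, labels)` /
`transform(activity)` with output dimension 3. The default backend is a
deterministic supervised linear projection — a shrinkage-regularized
discriminant axis (per-cell standardized class-mean difference divided by
`variance + γ`) plus the top two principal components of the residual
frame cloud, computed by deterministic power iteration — so the whole
pipeline runs offline; its validation loss is 1 − kNN accuracy, standing
in for the contrastive InfoNCE loss, and γ is its tunable hyperparameter.
A contrastive embedding (CEBRA, architecture "offset1-model",
temperature 1, 2000 iterations, output dimension 3) can be slotted in as
an external backend; this substitution is deliberate, not a
reimplementation. Non-distractor trials are balanced across sides, split
80/20 into train/test, hyperparameters are chosen by 5-fold
cross-validation (ties go to the first grid point), and the backend is
refit on the full training set.

Decoding is a cosine-distance kNN (k = 5) majority vote; relative
accuracy subtracts non-distractor test accuracy from distractor-subset
accuracy pointwise and averages a 1-s window following the distractor
(offset-anchored, consistent with the selectivity module). Region
contributions replace the activity of all other regions by their per-cell
mean before embedding.

# Resampling statistics

The one-tailed bootstrap resamples each group with replacement at its own
size (the resampling unit is whatever the caller passes — sessions,
pseudo-mice or networks — since the source text does not specify);
the statistic is the difference of means, and
`p = (1 + #violations)/(n_boot + 1)` with exact ties counted half. The
percentile scheme is anticonservative at very small samples (measured
null rejection 0.075 at n = 10 per group, 0.052 at n = 25, 0.050 at
n = 40, α = 0.05); calibration claims are made at n ≈ 30, matching the
session counts of the modeled study. Benjamini-Hochberg is the standard
step-up rule; a Bonferroni threshold helper covers the remaining figure
conventions. ANOVA-family statistics are delegated to standard R
routines by callers and are not re-implemented.

# Numerical choices and limitations

* Ridge systems are solved directly (`solve`), with an explicit
  singularity error for λ = 0 on rank-deficient designs.
* Cross-validation folds are contiguous blocks, reducing leakage through
  temporal autocorrelation.
* The RNN core is compiled (RcppArmadillo with in-place BLAS rank-one
  updates); all randomness uses the R RNG, so `set.seed()` reproduces
  training bit-for-bit.
* Session containers are HDF5 (`/activity`, `/region_of`, `/frame_rate`,
  trial table group and a mirrored CSV); configs are YAML; tables are
  CSV; the contrast summary is JSON.
* Known limitations: the generator's reduced preset couples attractor
  depth to coupling strength (real baseline selectivity was comparable
  across cohorts); the default embedding backend is linear; the
  one-tailed bootstrap is not exchangeability-based; FORCE training of
  raw arbitrary trial averages is out of reach at 64 units (see above),
  so network-level claims are relative to the reference-target family.
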