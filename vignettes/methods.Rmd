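---
title: "Models and methods behind bulbswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bulbswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

bulbswitch analyses calcium-imaging recordings from olfactory-bulb output
neurons while mice alternate between a fine odour discrimination (rewarded
mixture α vs the similar mixture α′) and a coarse one (α vs the dissimilar
β) inside one session (Fine1 → Coarse → Fine2). This vignette explains the
models and conventions the package implements, the choices that were
genuinely open, and what the synthetic-cohort generator does and does not
emulate. It states no empirical result beyond what the package's tests and
acceptance script themselves compute.

## Response quantification

**ΔF/F and baselines.** Fluorescence is converted per trial:
F₀ is the mean raw fluorescence over the `baseline_window` (default 2 s)
immediately preceding odour onset, and ΔF/F = (F − F₀)/F₀. The 2 s window
is a design choice — it fits comfortably inside the 20 s inter-trial
interval and tracks slow drift (bleaching) at the trial timescale. A
per-session baseline is not currently offered because the per-trial variant
dominates practice with drifting awake-animal recordings; the baseline
window length is a parameter everywhere it matters.

**Amplitude.** The odour-response amplitude is the arithmetic mean of ΔF/F
over the half-open 1 s odour window [onset, onset + 1 s) — 30 frames at the
default 30 Hz. Slow indicator kinetics make sub-second windows noisier, so
1 s is both the stimulus duration and the integration time.

**Significance of a response.** A response is significant when |a| strictly
exceeds 3 × the sd of *baseline fluctuations*. Crucially, the noise
statistic is matched to the signal statistic: the baseline sd is the
standard deviation of non-overlapping 1 s window means tiled over the
pre-odour inter-trial interval (up to 10 s, staying 3 s clear of the
previous trial's transient so its tail does not leak in). Comparing a
30-frame mean against a single-frame sd would misstate the threshold by a
factor of √30.

**Windows and time.** All windows are half-open [start, end); times are in
seconds with odour onset defining t = 0 within a trial; frames are indexed
from zero at acquisition times (j − 1)/rate. Trials whose odour window is
truncated by the end of a recording are dropped with a warning, never
imputed.

## Per-ROI statistics

**Selectivity.** For each ROI the α vs α′ amplitudes measured during the
fine epochs are compared with a pooled-variance two-sample t-test
(two-tailed). The t-score — not a z-score — is the selectivity currency
because each group holds only on the order of ten trials. The selectivity
index is s = |t|, and the preferred odour follows sign(t) (t > 0: α).
Zero-variance degenerate inputs (possible in noise-free synthetic data) are
resolved by convention: identical samples give t = 0, separated constant
samples give ±∞ with p = 0.

**Task modulation.** Per ROI, the α (rewarded, non-probe) amplitudes from
the two fine epochs are compared against the coarse-epoch α amplitudes with
the same pooled-variance two-tailed t-test; an ROI is *modulated* when
p < `alpha_level`. The default level of 0.05 is pinned by the design of the
shuffle control: a ~5% chance rate on a 353-ROI cohort corresponds to ~17–18
flagged ROIs. To balance slow drifts, Fine2 is first truncated from its end
to the Fine1 trial count (`equalize_fine_epochs()`); when Fine2 is already
the shorter epoch, both are kept whole with a warning, since discarding
Fine1 trials would have no counterpart in the protocol. Rewarded α′ probe
trials never enter any α pool.

**Shuffle control.** The test's false-positive behaviour is calibrated by
permuting the fine/coarse labels across each session's α S+ trials and
re-running the test. All ROIs of a session share the same trials, so one
permutation per session per shuffle is drawn and applied to every ROI —
group sizes are preserved exactly, and the per-ROI marginal null is the
same as independent permutation. The default is 100 shuffles (50 in the
calibration script, where the mean over shuffles converges quickly).

**Sniff confound.** Respiration is summarized per trial by the inhalation
count in the odour window, the sniff rate (count/window), and the
first-inhalation latency. Inhalation onsets are detected as negative-going
zero crossings of the mean-subtracted flow trace; flow-sensor polarity is
rig-specific, hence the `invert` switch. At the default 1 s window, count
and rate are the same number, so the default regressor set is rate +
latency; supplying all three simply exercises the collinearity guard, which
drops redundant columns with a warning. Residualization fits, per ROI, an
OLS model of amplitude on the regressors plus intercept — pooled across
tasks, because fitting within task would absorb part of the very task
effect under test (a within-task option remains available by subsetting) —
and replaces amplitudes by residuals. Missing latencies are mean-imputed so
the per-ROI trial count never changes. Because the features are shared by
all ROIs of a session, the residual projection is one QR solve per session.

A note on directionality: removing sniff variance raises the power of the
task test when sniff coupling is material. When coupling is weak, the raw
and residualized flagged *counts* differ mainly through false-positive
noise, so the residualized count is not guaranteed to be the larger one on
any single cohort; the property is tested in the strong-coupling regime
where it is a power statement rather than a coin flip.

**Switch-aligned time course.** For modulated ROIs, each α amplitude is
expressed relative to that ROI's Fine1 mean and averaged across ROIs at
each α-trial position within epoch. The first-coarse-trial change and its
two-sample t (position-1 values vs all Fine1 relative values, across ROIs)
quantify how immediate the modulation is; the first Fine2 position at which
p exceeds the level marks recovery.

## Population analyses

**Pseudo-population and PCA.** Condition-averaged ΔF/F transients (default
window −1 to +2 s around onset) are concatenated per ROI across conditions;
ROIs from all sessions are stacked as a pseudo-population. PCA treats
time-condition samples as observations and ROIs as variables: each ROI's
mean over all concatenated timepoints is subtracted and nothing is
variance-scaled, so components stay in ΔF/F units — the convention of the
state-space trajectory tradition. The transpose convention (ROIs as
observations) would analyse ROI-space geometry instead and is not what
trajectory plots show; the implemented orientation is documented here and
in `pca_trajectories()`. Eigenvector signs are arbitrary, so each
component's largest-magnitude loading is made positive. The default
condition set separates α-Fine1, α-Fine2 and α-coarse (plus α′-fine) so
task dependence can be compared against within-task reversibility;
`trajectory_separation()` averages PC1–3 distance over the odour second,
avoiding the pre-odour segment where all conditions coincide at noise
level.

**Correlation and ROI removal.** Per animal (per imaging location via
`group_by = "session"` — per-animal is the default because per-location ROI
counts can be small), the per-ROI mean α and α′ amplitude vectors from the
fine epochs are correlated (Pearson). The removal statistic is
(r_removed − r_full)/r_full, reported as a percentage; the random control
repeats the removal with size-matched random subsets. The normalization
makes the statistic meaningless when r_full is near zero — on cohorts with
realistic tuning r_full is high, and the worked tests use such regimes.

**Decoder.** Per session, single trials are labelled S+ vs S− from the
population amplitude vector by linear discriminant analysis with equal
priors. The trial count is routinely smaller than the ROI count, so the
pooled within-class covariance is shrunk toward its diagonal with an
analytically chosen weight (the off-diagonal variance-over-magnitude ratio,
clipped to [0, 1]); with ample data the weight tends to zero and the rule
approaches plain LDA, which is how it is cross-checked against a textbook
implementation in the tests. Training uses a stratified 2/3 split and
evaluation the held-out 1/3; accuracies are averaged over repeated random
splits (default 100) because a single split at these trial counts is
noisy.

## The synthetic generator

The generator exists to give every analysis stage a ground truth. Its
defaults are the study conditions: five animals totalling 353 ROIs; epochs
of 15–25 trials (each with ≤3 consecutive same-type trials, ≥4 rewarded and
≥2 non-rewarded trials, otherwise random); 1 s odour, 20 s ITI; rewarded α′
probes only in the coarse epoch, Poisson with mean 1.6 per session
(truncated so at least three coarse α trials always remain — a tail event
with no measurable effect on the mean); ~12% modulated ROIs, drawn from the
α-selective class, with a fine-epoch α amplification of 0.17 ΔF/F.

Per ROI, tuning is drawn as a gamma base amplitude (mean 0.3 ΔF/F), an
exponential α/α′ gap (mean 0.06 ΔF/F) split symmetrically around it, and an
independent β amplitude. Each trial adds a difference-of-exponentials
kernel (rise 0.05 s, decay 0.5 s — GCaMP6f-like; only the window mean
matters downstream, so kinetics shape realism, not correctness) scaled so
the odour-window mean ΔF/F equals the trial's true amplitude. Three noise
sources act: per-frame i.i.d. Gaussian noise (`noise_sd`, default 0.1
ΔF/F), a per-trial amplitude jitter (`amp_sd`, default 0.1 ΔF/F), and a
linear sniff coupling (`sniff_coupling` × (trial sniff rate − mean rate),
default 0.05 ΔF/F/Hz) shared by all ROIs of a trial. The amplitude jitter
is deliberate: window-averaging reduces frame noise to ~0.02 ΔF/F, far
below the trial-to-trial variability of real calcium responses, and
without realistic trial noise every population-level contrast saturates
and validates nothing. With all three set to zero, every downstream
amplitude estimate reproduces its ground-truth value to better than 1e-9 —
the construction-fidelity invariant the tests enforce. Sniff coupling is
linear by design so that it is exactly removable by the linear regression
the analysis applies.

Respiration is quasi-periodic: per-cycle rates are drawn from
N(4, 1) Hz (truncated at 0.5 Hz) and each cycle traces −sin(2π·phase), so
inhalation onsets are negative-going zero crossings at exactly known times.
Behaviour is Bernoulli correct/incorrect with a configurable lapse rate
(default 0.1) and stereotyped lick bursts inside the response window; there
is no reaction-time model, no post-switch error dynamics, no satiety.
The effect size of modulation is a single constant per cohort
(`modulation_delta`) rather than a distribution — the true across-neuron
distribution is unknown, so it is exposed as a knob instead of asserted.

What the generator does **not** emulate: raw movies and ROI segmentation,
neuropil/out-of-focus contamination, odour-plume and olfactometer dynamics
(responses are taken from valve onset; the olfactometer's ~0.4 s mixing
constant is deliberately not compensated), non-stationary arousal, and
correlated noise beyond the sniff common mode. Passing tests on synthetic
cohorts therefore validates the *estimators* — calibration, recovery,
directionality — not the biology of any particular recording.

One scoring subtlety carried over from the protocol: the reward was
available for 2 s from odour onset, but correctness is scored in the
1–2.5 s analysis window. The scorer follows the analysis window; the
discrepancy is surfaced here rather than silently resolved.

## Numerical conventions and problem sizes

Windows map to frames by half-open arithmetic with a 1e-9 guard against
floating-point edges. Session files round-trip bit-exactly: doubles are
printed with 17 significant digits in CSV/YAML and traces are stored as
little-endian float64 in a flat binary container with dimensions in the
YAML metadata. All randomness flows from one master seed through a
deterministic FNV-1a-based seed derivation (`derive_seed()`), so cohorts,
shuffles, removals and splits are independently reproducible; two runs with
the same configuration and seed produce byte-identical serialized outputs.

The test suite validates at the study scale where the claim depends on it —
353-ROI, five-animal cohorts for calibration, recovery, trajectory
geometry, correlation-removal direction (twenty independent cohorts) and
decoder comparisons (fifty split repeats) — and at reduced scale (tens of
ROIs, 6–12-trial epochs, shortened ITIs) for structural and oracle checks,
where the shorter baselines are sufficient. Exactness checks always use the
full 20 s ITI, because the calcium kernel's tail (~2.5 s) must clear the
baseline window for amplitudes to be recoverable to machine precision.

## Known limitations

- The correlation-change normalization is unstable for weakly correlated
  populations (r_full → 0).
- The shuffle control calibrates the marginal false-positive count, not the
  joint distribution across ROIs; sniff common-mode variability correlates
  ROI amplitudes within a session, widening the across-shuffle spread of
  flagged counts without moving its mean.
- The decoder's analytic shrinkage targets the diagonal; structured noise
  (e.g. the sniff common mode) is handled only insofar as the leading
  within-class directions survive shrinkage.
- Lick-pattern regression is out of scope; the behavioural scorer is the
  only lick-based analysis.
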