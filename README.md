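# bulbswitch

Analysis pipeline for two-photon calcium imaging of olfactory-bulb output
neurons (mitral/tufted cells, M/TCs) recorded while head-fixed mice switch,
within a session, between two go/no-go odour discriminations:

- **fine**: rewarded mixture α (40/60 blend of odorants A and B) vs the
  non-rewarded, highly similar mixture α′ (60/40 of the same odorants);
- **coarse**: the same rewarded α vs a dissimilar odour pair β.

Sessions run Fine1 → Coarse → Fine2 (15–25 trials per epoch, 1 s odour,
20 s inter-trial interval). Because α and its reward contingency are
identical in both tasks, any change in the α response isolates the effect of
task demand. The package quantifies that change per neuron and at the
population level, and ships a fully ground-truthed synthetic cohort
generator so every stage can be validated by parameter recovery.

## What it computes

For an ROI × frame fluorescence matrix plus a trial table, lick times and a
respiration trace:

- **Response amplitude** — ΔF/F = (F − F₀)/F₀ with per-trial baseline F₀;
  the amplitude *a* is the mean ΔF/F over the 1 s odour window. Responses
  are *significant* when |a| > 3 × sd of baseline 1 s window means.
- **Stimulus selectivity** — per ROI, the pooled-variance two-sample t-score
  *t* comparing α vs α′ amplitudes during fine discrimination; the
  selectivity index is s = |t| and the preferred odour follows sign(t).
- **Task modulation** — per ROI, a two-tailed two-sample t-test of α (S+)
  amplitudes, fine (Fine1 + Fine2, trial counts equalized) vs coarse, with a
  within-session label-permutation **shuffle control** that calibrates the
  false-positive count, and a **sniff-residualized** variant in which
  amplitudes are first regressed (OLS) on per-trial sniff rate and
  first-inhalation latency.
- **Population analyses** — pseudo-population PCA trajectories per (odour,
  task) condition; Pearson correlation between the per-ROI mean α and α′
  response vectors, and its relative change
  (r_removed − r_full)/r_full when the task-modulated ROIs (or size-matched
  random sets) are removed; a linear-discriminant S+/S− decoder (equal
  priors, pooled covariance shrunk analytically toward its diagonal)
  evaluated on repeated stratified 2/3–1/3 trial splits.
- **Behaviour** — a trial is correct when licking (S+) or withholding (S−)
  in the 1–2.5 s window after odour onset; switch-aligned accuracy curves
  across sessions.

The synthetic generator draws per-ROI tuning (α-/α′-selective/untuned),
builds GCaMP6f-like difference-of-exponential transients whose odour-window
mean equals the true amplitude, amplifies α responses of a modulated
subpopulation (~12% of ROIs, +0.17 ΔF/F) during fine epochs only, couples
amplitudes linearly to the trial's sniff rate, and emits exact ground truth
for selectivity, modulation and respiration timing.

## Worked example

```r
library(bulbswitch)

cfg <- synth_config()            # the study-scale defaults: 353 ROIs, 5 animals
cohort <- generate_cohort(cfg, seed = 42)
responses <- cohort_responses(cohort, equalize = TRUE)

modulation <- task_modulation_test(responses, alpha_level = 0.05)
shuffle    <- shuffle_control(responses, n_shuffles = 50, seed = 1)
print(modulation)
print(shuffle)
```

```
Task modulation (raw): 53/353 ROIs flagged at alpha = 0.05
  mean fine - coarse alpha response: +0.027 dF/F (flagged ROIs: +0.141)
Shuffle control: 18.74/353 ROIs flagged on average over 50 permutations (nominal 17.65)
```

53 of 353 ROIs change their α response significantly with task (the shuffle
control shows ~18–19 would be flagged by chance at the 5% level), and the
flagged ROIs gain ~0.14 ΔF/F during fine discrimination. Continuing:

```r
selectivity <- selectivity_tscore(responses)
print(selectivity_enrichment(selectivity, modulation))
mset <- modulation[modulation$modulated, c("animal_id", "session_id", "roi")]
print(removal_correlation_change(responses, mset, seed = 1))
print(switching_timecourse(responses, mset))
```

```
Selectivity enrichment: KS = 0.56 (p = 1.47e-12), 53 modulated vs 300 non-modulated ROIs
  38% of selective ROIs modulated vs 15% overall
alpha/alpha' correlation change over 5 group(s):
  removal set: mean change = +8.78%; size-matched random: -0.11%
Switch-aligned time course over 53 modulated ROIs
  first coarse alpha trial: -0.149 +/- 0.021 dF/F (t = -9.73, p = 9.95e-21, n = 53)
  Fine2 responses indistinguishable from Fine1 from alpha-trial position 1
```

Task-modulated ROIs are strongly enriched for stimulus selectivity;
removing them makes the α/α′ population vectors *more* correlated (harder
to tell apart) than removing random ROIs; and the amplification disappears
on the very first coarse trial after the switch. `run_pipeline(cfg, seed)`
chains all stages (including PCA trajectories and decoders) and
`make_report()` renders tables and figures.

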