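# Shared fixtures. Expensive cohorts are built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small, fast config: short epochs and ITI. Not suitable for exactness checks
# (the previous trial's calcium tail overlaps the short baseline) — use
# noiseless_config() for those.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_animals = 1, rois_per_animal = 12, epoch_lengths = c(8, 8, 8),
         iti = 6, pre_time = 8),
    list(...))
  do.call(synth_config, args)
}

# Noise-free config at the default 20 s ITI so window-mean amplitudes recover
# ground truth to machine precision.
noiseless_config <- function(...) {
  args <- utils::modifyList(
    list(n_animals = 1, rois_per_animal = 8, epoch_lengths = c(6, 6, 6),
         noise_sd = 0, amp_sd = 0, sniff_coupling = 0, lapse_rate = 0),
    list(...))
  do.call(synth_config, args)
}

# The suite's standard full-scale cohort (353 ROIs, 5 animals, defaults).
std_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(synth_config(), seed = 42)
  }
  .fixtures$cohort
}

std_responses <- function() {
  if (is.null(.fixtures$responses)) {
    .fixtures$responses <- suppressWarnings(
      cohort_responses(std_cohort(), equalize = TRUE))
  }
  .fixtures$responses
}

std_modulation <- function() {
  if (is.null(.fixtures$modulation)) {
    .fixtures$modulation <- task_modulation_test(std_responses())
  }
  .fixtures$modulation
}

# Hand-built minimal session: constant-baseline traces with known dF/F
# excursions, explicit trials and licks. `signal` is an optional
# n_rois x n_frames dF/F matrix added on top of baseline_f.
make_session <- function(onsets, rewarded, epoch, odour,
                         n_rois = 2, frame_rate = 30, duration = NULL,
                         baseline_f = 100, signal = NULL, licks = NULL,
                         probe = NULL) {
  if (is.null(duration)) duration <- max(onsets) + 5
  n_frames <- round(duration * frame_rate)
  traces <- matrix(baseline_f, n_rois, n_frames)
  if (!is.null(signal)) traces <- baseline_f * (1 + signal)
  n <- length(onsets)
  if (is.null(licks)) licks <- replicate(n, numeric(0), simplify = FALSE)
  trials <- data.frame(trial_id = seq_len(n), epoch = epoch,
                       task = ifelse(epoch == "Coarse", "coarse", "fine"),
                       odour = odour, rewarded = rewarded,
                       probe = if (is.null(probe)) FALSE else probe,
                       odour_onset = onsets,
                       outcome = "correct", stringsAsFactors = FALSE)
  trials$lick_times <- I(licks)
  new_ob_session(trials, traces, sniff = rep(0, n_frames),
                 frame_rate = frame_rate)
}

# Minimal response_table builder: one session, amplitudes supplied per ROI
# as a list of data.frames or via vectors.
make_response_table <- function(roi, trial_id, epoch, task, odour, rewarded,
                                amplitude, probe = FALSE,
                                animal_id = "a1", session_id = "s1") {
  d <- data.frame(animal_id = animal_id, session_id = session_id,
                  roi = roi, trial_id = trial_id, epoch = epoch, task = task,
                  odour = odour, rewarded = rewarded, probe = probe,
                  amplitude = amplitude, f0 = 100, baseline_sd = 0.01,
                  significant = NA, stringsAsFactors = FALSE)
  class(d) <- c("response_table", "data.frame")
  d
}
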