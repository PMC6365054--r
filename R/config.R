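#' Synthetic-cohort generator configuration
#'
#' Bundles every parameter of the synthetic task-switching cohort generator.
#' Defaults emulate the study conditions of the imaged cohort: five animals
#' totalling 353 ROIs, ~30 Hz acquisition, three-epoch sessions
#' (Fine1 -> Coarse -> Fine2) of 15-25 trials each, 1 s odour presentations
#' separated by a 20 s inter-trial interval, rewarded alpha-prime probe trials
#' at an average of 1.6 per session, ~12% task-modulated ROIs whose alpha
#' responses are amplified by 0.17 dF/F during fine discrimination, and
#' sniff-coupled trial-to-trial variability.
#'
#' @param n_animals number of animals (one session each).
#' @param rois_per_animal integer vector of ROI counts per animal, recycled to
#'   `n_animals`. Default splits 353 ROIs as evenly as possible over 5 animals.
#' @param frame_rate acquisition rate, Hz.
#' @param epoch_range inclusive range (length 2) from which each epoch's trial
#'   count is drawn uniformly.
#' @param epoch_lengths optional fixed trial counts `c(Fine1, Coarse, Fine2)`;
#'   overrides `epoch_range` when non-NULL.
#' @param odour_duration odour presentation, seconds.
#' @param iti inter-trial interval, seconds (odour offset to next onset).
#' @param pre_time quiet period before the first odour onset, seconds.
#' @param probe_rate expected rewarded alpha-prime probe trials per session
#'   (Poisson mean, truncated to the coarse epoch's rewarded slots).
#' @param kernel_rise,kernel_decay GCaMP6f-like difference-of-exponentials
#'   kernel time constants, seconds.
#' @param baseline_f resting fluorescence, arbitrary units.
#' @param noise_sd per-frame i.i.d. Gaussian noise, dF/F units.
#' @param amp_sd per-trial response-amplitude jitter, dF/F units. Models the
#'   trial-to-trial variability of calcium responses that per-frame shot noise
#'   alone cannot reproduce.
#' @param frac_alpha_selective,frac_alphaprime_selective expected proportions
#'   of ROIs preferring the alpha / alpha-prime odour.
#' @param frac_modulated expected proportion of task-modulated ROIs (drawn from
#'   the alpha-selective class).
#' @param modulation_delta additive amplification of the alpha response during
#'   fine-discrimination epochs for modulated ROIs, dF/F units.
#' @param sel_gap_mean mean of the exponential distribution of the per-ROI
#'   alpha vs alpha-prime amplitude gap, dF/F units.
#' @param base_amp_shape,base_amp_scale gamma parameters of the per-ROI base
#'   response amplitude, dF/F units.
#' @param sniff_rate_mean,sniff_rate_sd respiration rate mean and per-cycle sd,
#'   Hz.
#' @param sniff_coupling linear coupling of response amplitude to the trial's
#'   odour-window sniff rate, dF/F per Hz.
#' @param lapse_rate probability that the simulated animal responds
#'   incorrectly on a trial.
#' @param min_nonrewarded minimum non-rewarded trials per epoch (keeps the
#'   fine-epoch selectivity contrast estimable).
#' @param seed default master seed attached to the config (generator functions
#'   accept an explicit seed that takes precedence).
#' @return an object of class `synth_config` (a validated named list).
#' @examples
#' cfg <- synth_config(n_animals = 1, rois_per_animal = 10)
#' cfg$frame_rate
#' @export
synth_config <- function(n_animals = 5,
                         rois_per_animal = NULL,
                         frame_rate = 30,
                         epoch_range = c(15L, 25L),
                         epoch_lengths = NULL,
                         odour_duration = 1,
                         iti = 20,
                         pre_time = 20,
                         probe_rate = 1.6,
                         kernel_rise = 0.05,
                         kernel_decay = 0.5,
                         baseline_f = 100,
                         noise_sd = 0.1,
                         amp_sd = 0.1,
                         frac_alpha_selective = 0.35,
                         frac_alphaprime_selective = 0.25,
                         frac_modulated = 0.12,
                         modulation_delta = 0.17,
                         sel_gap_mean = 0.06,
                         base_amp_shape = 4,
                         base_amp_scale = 0.075,
                         sniff_rate_mean = 4,
                         sniff_rate_sd = 1,
                         sniff_coupling = 0.05,
                         lapse_rate = 0.1,
                         min_nonrewarded = 2,
                         seed = 1L) {
  if (is.null(rois_per_animal)) {
    total <- 353L
    base <- total %/% n_animals
    extra <- total %% n_animals
    rois_per_animal <- rep(base, n_animals) + c(rep(1L, extra),
                                                rep(0L, n_animals - extra))
  } else {
    rois_per_animal <- rep_len(as.integer(rois_per_animal), n_animals)
  }
  cfg <- list(
    n_animals = as.integer(n_animals),
    rois_per_animal = rois_per_animal,
    frame_rate = frame_rate,
    epoch_range = as.integer(epoch_range),
    epoch_lengths = if (!is.null(epoch_lengths)) as.integer(epoch_lengths),
    odour_duration = odour_duration,
    iti = iti,
    pre_time = pre_time,
    probe_rate = probe_rate,
    kernel_rise = kernel_rise,
    kernel_decay = kernel_decay,
    baseline_f = baseline_f,
    noise_sd = noise_sd,
    amp_sd = amp_sd,
    frac_alpha_selective = frac_alpha_selective,
    frac_alphaprime_selective = frac_alphaprime_selective,
    frac_modulated = frac_modulated,
    modulation_delta = modulation_delta,
    sel_gap_mean = sel_gap_mean,
    base_amp_shape = base_amp_shape,
    base_amp_scale = base_amp_scale,
    sniff_rate_mean = sniff_rate_mean,
    sniff_rate_sd = sniff_rate_sd,
    sniff_coupling = sniff_coupling,
    lapse_rate = lapse_rate,
    min_nonrewarded = as.integer(min_nonrewarded),
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks the invariants every generator function relies on: positive rates
#' and durations, proportions in `[0, 1]` summing to at most 1, non-negative
#' modulation, and a feasible epoch-length range.
#'
#' @param cfg a `synth_config`.
#' @return `cfg`, invisibly, or an error naming the offending field.
#' @export
validate_synth_config <- function(cfg) {
  chk <- function(ok, field, msg) if (!ok) .stop_field(field, msg)
  chk(cfg$n_animals >= 1, "n_animals", "must be >= 1")
  chk(all(cfg$rois_per_animal >= 1), "rois_per_animal", "must be >= 1")
  chk(cfg$frame_rate > 0, "frame_rate", "must be > 0")
  chk(cfg$odour_duration > 0, "odour_duration", "must be > 0")
  chk(cfg$iti > 0, "iti", "must be > 0")
  props <- c(cfg$frac_alpha_selective, cfg$frac_alphaprime_selective,
             cfg$frac_modulated)
  chk(all(props >= 0 & props <= 1), "frac_*", "proportions must lie in [0, 1]")
  chk(cfg$frac_alpha_selective + cfg$frac_alphaprime_selective <= 1,
      "frac_*_selective", "selective proportions must sum to <= 1")
  chk(cfg$frac_modulated <= cfg$frac_alpha_selective, "frac_modulated",
      "modulated ROIs are drawn from the alpha-selective class, so frac_modulated must not exceed frac_alpha_selective")
  chk(cfg$modulation_delta >= 0, "modulation_delta", "must be >= 0")
  chk(cfg$kernel_rise > 0 && cfg$kernel_decay > 0, "kernel_rise/kernel_decay",
      "kernel time constants must be > 0")
  chk(cfg$kernel_rise < cfg$kernel_decay, "kernel_rise",
      "rise constant must be smaller than decay constant")
  chk(cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(cfg$amp_sd >= 0, "amp_sd", "must be >= 0")
  chk(cfg$baseline_f > 0, "baseline_f", "must be > 0")
  chk(cfg$sniff_rate_mean > 0, "sniff_rate_mean", "must be > 0")
  chk(cfg$sniff_rate_sd >= 0, "sniff_rate_sd", "must be >= 0")
  chk(cfg$lapse_rate >= 0 && cfg$lapse_rate <= 1, "lapse_rate",
      "must lie in [0, 1]")
  chk(cfg$probe_rate >= 0, "probe_rate", "must be >= 0")
  rng <- if (!is.null(cfg$epoch_lengths)) range(cfg$epoch_lengths) else cfg$epoch_range
  chk(rng[1] >= 4 + cfg$min_nonrewarded, "epoch_range",
      sprintf("epochs of %d trials cannot hold >= 4 rewarded and >= %d non-rewarded trials",
              rng[1], cfg$min_nonrewarded))
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic task-switching cohort configuration\n")
  cat(sprintf("  %d animal(s), ROIs per animal: %s (total %d)\n",
              x$n_animals, paste(x$rois_per_animal, collapse = "/"),
              sum(x$rois_per_animal)))
  cat(sprintf("  epochs Fine1/Coarse/Fine2, %s trials each; odour %g s, ITI %g s\n",
              if (is.null(x$epoch_lengths))
                paste(x$epoch_range, collapse = "-")
              else paste(x$epoch_lengths, collapse = "/"),
              x$odour_duration, x$iti))
  cat(sprintf("  probe rate %g/session; frame rate %g Hz\n",
              x$probe_rate, x$frame_rate))
  cat(sprintf("  selective fractions: alpha %g, alpha' %g; modulated %g (delta %g dF/F)\n",
              x$frac_alpha_selective, x$frac_alphaprime_selective,
              x$frac_modulated, x$modulation_delta))
  cat(sprintf("  noise: frame sd %g, trial amplitude sd %g; sniff %g +/- %g Hz, coupling %g dF/F/Hz\n",
              x$noise_sd, x$amp_sd, x$sniff_rate_mean, x$sniff_rate_sd,
              x$sniff_coupling))
  invisible(x)
}
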