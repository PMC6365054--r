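# Synthetic cohort generator: trial sequences, respiration, ROI traces,
# sessions and cohorts, all with attached ground truth.

EPOCHS <- c("Fine1", "Coarse", "Fine2")

#' Generate a three-epoch go/no-go trial sequence
#'
#' Draws one session's trial design: a Fine1, Coarse and Fine2 epoch, each
#' 15-25 trials long by default, with a random rewarded/non-rewarded sequence
#' constrained so that no more than three consecutive trials are of the same
#' type and each epoch contains at least four rewarded trials (and at least
#' `min_nonrewarded` non-rewarded ones). During the coarse epoch a
#' Poisson-distributed number of rewarded trials (mean `probe_rate`, truncated
#' to the number of rewarded slots) is converted to rewarded alpha-prime
#' "probe" presentations.
#'
#' Odour assignment: fine epochs present alpha (rewarded) vs alpha-prime
#' (non-rewarded); the coarse epoch presents alpha (rewarded, except probes)
#' vs beta (non-rewarded).
#'
#' @param config a [synth_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return data frame with one row per trial: `trial_id`, `epoch`, `task`,
#'   `odour`, `rewarded`, `probe`.
#' @export
generate_trial_sequence <- function(config, seed = config$seed) {
  validate_synth_config(config)
  with_seed(seed, {
    per_epoch <- lapply(seq_along(EPOCHS), function(e) {
      len <- if (!is.null(config$epoch_lengths)) {
        config$epoch_lengths[e]
      } else if (config$epoch_range[1] == config$epoch_range[2]) {
        config$epoch_range[1]
      } else {
        sample(seq.int(config$epoch_range[1], config$epoch_range[2]), 1L)
      }
      rewarded <- .draw_epoch_sequence(len, config$min_nonrewarded)
      data.frame(epoch = EPOCHS[e],
                 task = if (EPOCHS[e] == "Coarse") "coarse" else "fine",
                 rewarded = rewarded,
                 stringsAsFactors = FALSE)
    })
    trials <- do.call(rbind, per_epoch)
    trials$trial_id <- seq_len(nrow(trials))
    trials$odour <- ifelse(trials$rewarded, "alpha",
                           ifelse(trials$task == "fine", "alphaprime", "beta"))
    trials$probe <- FALSE
    # probes are drawn Poisson(probe_rate) but always leave >= 3 rewarded
    # alpha trials in the coarse epoch so the fine-vs-coarse contrast stays
    # estimable (the truncation is far in the Poisson tail and does not move
    # the long-run mean detectably)
    splus_coarse <- which(trials$epoch == "Coarse" & trials$rewarded)
    n_probe <- min(stats::rpois(1L, config$probe_rate),
                   max(0L, length(splus_coarse) - 3L))
    if (n_probe > 0) {
      probe_idx <- if (length(splus_coarse) == 1L) splus_coarse else
        sample(splus_coarse, n_probe)
      trials$probe[probe_idx] <- TRUE
      trials$odour[probe_idx] <- "alphaprime"
    }
    trials[, c("trial_id", "epoch", "task", "odour", "rewarded", "probe")]
  })
}

# Rejection-sample a rewarded/non-rewarded sequence of length `len` with
# run length <= 3, >= 4 rewarded and >= min_nr non-rewarded trials.
.draw_epoch_sequence <- function(len, min_nr, max_tries = 10000L) {
  if (len < 4 + min_nr) {
    stop(sprintf(
      "epoch of %d trials cannot satisfy >= 4 rewarded and >= %d non-rewarded trials",
      len, min_nr), call. = FALSE)
  }
  for (i in seq_len(max_tries)) {
    s <- sample(c(TRUE, FALSE), len, replace = TRUE)
    if (sum(s) < 4 || sum(!s) < min_nr) next
    if (max(rle(s)$lengths) > 3) next
    return(s)
  }
  stop("could not draw a trial sequence satisfying the run-length and count constraints",
       call. = FALSE)
}

#' Draw per-ROI ground-truth tuning and modulation labels
#'
#' Each ROI is assigned a selectivity class (alpha, alphaprime or none, with
#' configured expected proportions), a base response amplitude (gamma
#' distributed), a selectivity gap (exponential) split symmetrically between
#' the preferred and non-preferred A/B mixture, an independent beta-odour
#' amplitude, and a task-modulation flag. Modulated ROIs are drawn from the
#' alpha-selective class (conditional probability
#' `frac_modulated / frac_alpha_selective`, so the marginal modulated fraction
#' matches `frac_modulated`) and carry `delta = modulation_delta`; all other
#' ROIs have `delta = 0`.
#'
#' @param config a [synth_config()].
#' @param n_rois number of ROIs.
#' @param seed integer seed.
#' @return data frame of class `ground_truth`: `roi`, `selectivity_class`,
#'   `amp_alpha`, `amp_alphaprime`, `amp_beta`, `modulated`, `delta` (dF/F).
#' @export
generate_ground_truth <- function(config, n_rois, seed = config$seed) {
  validate_synth_config(config)
  with_seed(seed, {
    cls <- sample(c("alpha", "alphaprime", "none"), n_rois, replace = TRUE,
                  prob = c(config$frac_alpha_selective,
                           config$frac_alphaprime_selective,
                           1 - config$frac_alpha_selective -
                             config$frac_alphaprime_selective))
    base <- stats::rgamma(n_rois, shape = config$base_amp_shape,
                          scale = config$base_amp_scale)
    gap <- 0.005 + stats::rexp(n_rois, rate = 1 / config$sel_gap_mean)
    gap[cls == "none"] <- 0
    amp_alpha <- base + ifelse(cls == "alpha", gap / 2,
                               ifelse(cls == "alphaprime", -gap / 2, 0))
    amp_alphaprime <- base + ifelse(cls == "alpha", -gap / 2,
                                    ifelse(cls == "alphaprime", gap / 2, 0))
    amp_beta <- stats::rgamma(n_rois, shape = config$base_amp_shape,
                              scale = config$base_amp_scale)
    p_mod <- if (config$frac_alpha_selective > 0)
      config$frac_modulated / config$frac_alpha_selective else 0
    modulated <- cls == "alpha" & stats::runif(n_rois) < p_mod
    gt <- data.frame(roi = seq_len(n_rois),
                     selectivity_class = cls,
                     amp_alpha = amp_alpha,
                     amp_alphaprime = amp_alphaprime,
                     amp_beta = amp_beta,
                     modulated = modulated,
                     delta = ifelse(modulated, config$modulation_delta, 0),
                     stringsAsFactors = FALSE)
    class(gt) <- c("ground_truth", "data.frame")
    gt
  })
}

#' Generate a quasi-periodic respiration trace
#'
#' Concatenates sniff cycles whose instantaneous rates are drawn i.i.d. from
#' `N(sniff_rate_mean, sniff_rate_sd)` (truncated at 0.5 Hz). Within cycle
#' `k`, starting at onset `t_k`, the trace is `-sin(2 * pi * phase)`, so each
#' inhalation onset is a negative-going zero crossing — the convention the
#' sniff-feature extractor detects.
#'
#' @param config a [synth_config()].
#' @param duration trace duration, seconds (> 0).
#' @param seed integer seed.
#' @return list with `trace` (length `round(duration * frame_rate)`) and
#'   `onsets`, the exact inhalation-onset times in seconds.
#' @export
generate_sniff_trace <- function(config, duration, seed = config$seed) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  with_seed(seed, {
    n_frames <- round(duration * config$frame_rate)
    # draw more cycles than can possibly fit, then trim
    n_draw <- ceiling(duration * max(config$sniff_rate_mean +
                                       4 * config$sniff_rate_sd, 1)) + 8L
    rates <- stats::rnorm(n_draw, config$sniff_rate_mean, config$sniff_rate_sd)
    rates <- pmax(rates, 0.5)
    onsets <- cumsum(c(0, 1 / rates))
    while (onsets[length(onsets)] < duration) {
      r <- max(stats::rnorm(1, config$sniff_rate_mean, config$sniff_rate_sd), 0.5)
      rates <- c(rates, r)
      onsets <- c(onsets, onsets[length(onsets)] + 1 / r)
    }
    tt <- (seq_len(n_frames) - 1) / config$frame_rate
    cycle <- findInterval(tt, onsets)
    phase <- (tt - onsets[cycle]) * rates[cycle]
    list(trace = -sin(2 * pi * phase),
         onsets = onsets[onsets < duration])
  })
}

# Unit-integral (over the odour window) GCaMP-like kernel: for a trial at
# `onset`, returns frame indices and kernel values scaled so that the mean
# over the odour-window frames is exactly 1.
.trial_kernel <- function(onset, config, n_frames, support = 10) {
  fr <- config$frame_rate
  kf <- window_frames(onset, onset + support, fr, n_frames)
  if (!length(kf)) return(NULL)
  tau <- (kf - 1) / fr - onset
  k <- exp(-tau / config$kernel_decay) - exp(-tau / config$kernel_rise)
  wf <- window_frames(onset, onset + config$odour_duration, fr, n_frames)
  m <- mean(k[match(wf, kf)])
  if (!is.finite(m) || m <= 0) stop("degenerate response kernel", call. = FALSE)
  list(frames = kf, kernel = k / m)
}

#' Synthesize ROI fluorescence traces for a trial sequence
#'
#' Builds the raw fluorescence matrix: for every trial, a
#' difference-of-exponentials calcium kernel is added, scaled so the mean
#' dF/F over the odour window equals the ROI's true amplitude for that odour
#' and task — including the fine-epoch amplification `delta` for modulated
#' ROIs on alpha trials — plus `sniff_coupling * (trial sniff rate - mean
#' rate)`, plus a per-trial amplitude jitter of sd `amp_sd`. Per-frame i.i.d.
#' Gaussian noise of sd `noise_sd` (dF/F units) is added and the result is
#' returned on the raw-fluorescence scale `baseline_f * (1 + dF/F)`.
#'
#' @param trials trial table with `odour_onset`, `odour`, `task`, `probe`.
#' @param ground_truth a [generate_ground_truth()] table.
#' @param sniff list from [generate_sniff_trace()] covering the session.
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @param n_frames number of frames in the session.
#' @return `n_rois x n_frames` matrix of raw fluorescence.
#' @export
generate_roi_traces <- function(trials, ground_truth, sniff, config,
                                seed = config$seed,
                                n_frames = length(sniff$trace)) {
  validate_synth_config(config)
  fr <- config$frame_rate
  last_needed <- max(trials$odour_onset) + config$odour_duration
  if (round(last_needed * fr) > n_frames) {
    stop("trial timing does not fit within the session duration", call. = FALSE)
  }
  n_rois <- nrow(ground_truth)
  with_seed(seed, {
    signal <- matrix(0, n_rois, n_frames)
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      amp <- switch(tr$odour,
                    alpha = ground_truth$amp_alpha,
                    alphaprime = ground_truth$amp_alphaprime,
                    beta = ground_truth$amp_beta)
      if (tr$odour == "alpha" && tr$task == "fine") {
        amp <- amp + ground_truth$delta
      }
      rate <- sum(sniff$onsets >= tr$odour_onset &
                    sniff$onsets < tr$odour_onset + config$odour_duration) /
        config$odour_duration
      amp <- amp + config$sniff_coupling * (rate - config$sniff_rate_mean)
      if (config$amp_sd > 0) {
        amp <- amp + stats::rnorm(n_rois, 0, config$amp_sd)
      }
      kk <- .trial_kernel(tr$odour_onset, config, n_frames)
      if (is.null(kk)) next
      signal[, kk$frames] <- signal[, kk$frames] + outer(amp, kk$kernel)
    }
    if (config$noise_sd > 0) {
      signal <- signal + matrix(stats::rnorm(n_rois * n_frames, 0, config$noise_sd),
                                n_rois, n_frames)
    }
    config$baseline_f * (1 + signal)
  })
}

#' Generate one complete synthetic session
#'
#' Assembles the trial sequence (with onset times on the configured
#' odour/ITI grid), respiration trace, ground-truth tuning, ROI traces and
#' simulated lick behaviour (Bernoulli correct/incorrect with probability
#' `1 - lapse_rate`; licks fall inside the 1-2.5 s response window).
#'
#' @param config a [synth_config()].
#' @param seed integer master seed for this session.
#' @param animal_id,session_id identifiers stored in the session.
#' @param n_rois number of ROIs (defaults to the first entry of
#'   `config$rois_per_animal`).
#' @return list with `session` (class `ob_session`) and `ground_truth`.
#' @export
generate_session <- function(config, seed = config$seed,
                             animal_id = "a1", session_id = "s1",
                             n_rois = config$rois_per_animal[1]) {
  validate_synth_config(config)
  trials <- generate_trial_sequence(config, derive_seed(seed, "trials"))
  n <- nrow(trials)
  trials$odour_onset <- config$pre_time +
    (seq_len(n) - 1) * (config$odour_duration + config$iti)
  duration <- trials$odour_onset[n] + config$odour_duration + 15
  n_frames <- round(duration * config$frame_rate)
  sniff <- generate_sniff_trace(config, duration, derive_seed(seed, "sniff"))
  gt <- generate_ground_truth(config, n_rois, derive_seed(seed, "gt"))
  traces <- generate_roi_traces(trials, gt, sniff, config,
                                derive_seed(seed, "traces"), n_frames)
  beh <- with_seed(derive_seed(seed, "licks"), {
    correct <- stats::runif(n) >= config$lapse_rate
    licks <- vector("list", n)
    for (i in seq_len(n)) {
      on <- trials$odour_onset[i]
      lick_now <- (trials$rewarded[i] && correct[i]) ||
        (!trials$rewarded[i] && !correct[i])
      licks[[i]] <- if (lick_now) on + c(1.1, 1.4, 1.7) else numeric(0)
    }
    list(correct = correct, licks = licks)
  })
  trials$outcome <- ifelse(beh$correct, "correct", "incorrect")
  trials$lick_times <- I(beh$licks)
  session <- new_ob_session(trials = trials, traces = traces,
                            sniff = sniff$trace,
                            frame_rate = config$frame_rate,
                            animal_id = animal_id, session_id = session_id)
  list(session = session, ground_truth = gt)
}

#' Generate a synthetic cohort
#'
#' One session per animal; per-animal seeds are derived deterministically
#' from the master seed so animals have disjoint random streams. The default
#' configuration yields 5 animals totalling 353 ROIs.
#'
#' @param config a [synth_config()].
#' @param seed integer master seed.
#' @return object of class `ob_cohort`: a list of `list(session, ground_truth)`.
#' @examples
#' coh <- generate_cohort(synth_config(n_animals = 2, rois_per_animal = 5,
#'                                     epoch_lengths = c(8, 8, 8), iti = 4,
#'                                     pre_time = 6), seed = 1)
#' length(coh)
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_synth_config(config)
  cohort <- lapply(seq_len(config$n_animals), function(a) {
    generate_session(config,
                     seed = derive_seed(seed, paste0("animal", a)),
                     animal_id = sprintf("animal%02d", a),
                     session_id = sprintf("session%02d", a),
                     n_rois = config$rois_per_animal[a])
  })
  class(cohort) <- "ob_cohort"
  cohort
}

#' @export
print.ob_cohort <- function(x, ...) {
  n_rois <- sum(vapply(x, function(el) nrow(el$session$traces), 0))
  cat(sprintf("Synthetic cohort: %d session(s), %d ROIs total\n",
              length(x), n_rois))
  invisible(x)
}
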