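# From traces to per-trial dF/F response amplitudes, significance flags and
# per-ROI stimulus selectivity.

#' Compute per-trial dF/F and baseline statistics
#'
#' For every trial, `F0` is the mean raw fluorescence over the
#' `baseline_window` seconds immediately preceding odour onset (per ROI, per
#' trial), and `dF/F = (F - F0) / F0`. Each frame belongs to the trial whose
#' peri-trial segment covers it (segments run from one trial's baseline start
#' to the next trial's baseline start; the first/last segments extend to the
#' trace edges).
#'
#' The "baseline fluctuation" statistic is matched to the signal statistic:
#' the response amplitude is a 1 s window mean, so the baseline sd is the
#' standard deviation of non-overlapping 1 s window means of dF/F tiled over
#' the inter-trial interval preceding each onset (up to `tile_span` seconds,
#' keeping clear of the previous trial's transient).
#'
#' @param session an `ob_session`.
#' @param baseline_window seconds before odour onset used for `F0`.
#' @param tile_span maximum span (s) of the pre-onset period tiled with 1 s
#'   windows for the baseline sd.
#' @param guard seconds after the previous odour onset excluded from the tiled
#'   period (lets the previous calcium transient decay).
#' @return object of class `dff_result`: `dff` (matrix, same shape as the
#'   traces), `f0` and `baseline_sd` (`n_rois x n_trials`), plus the trial
#'   table and frame rate.
#' @export
compute_dff <- function(session, baseline_window = 2, tile_span = 10,
                        guard = 3) {
  validate_session(session)
  tr <- session$trials
  if (nrow(tr) == 0) stop("session has no trials", call. = FALSE)
  fr <- session$frame_rate
  n_frames <- ncol(session$traces)
  n_rois <- nrow(session$traces)
  n_trials <- nrow(tr)
  if (tr$odour_onset[1] < baseline_window) {
    .stop_field("odour_onset",
                sprintf("first onset at %.2f s leaves no %.2f s baseline window",
                        tr$odour_onset[1], baseline_window))
  }
  seg_start <- floor((tr$odour_onset - baseline_window) * fr + 1e-9) + 1
  seg_start[1] <- 1
  seg_end <- c(seg_start[-1] - 1, n_frames)
  f0 <- matrix(NA_real_, n_rois, n_trials)
  bsd <- matrix(NA_real_, n_rois, n_trials)
  dff <- matrix(NA_real_, n_rois, n_frames)
  for (t in seq_len(n_trials)) {
    on <- tr$odour_onset[t]
    bframes <- window_frames(on - baseline_window, on, fr, n_frames)
    f0[, t] <- rowMeans(session$traces[, bframes, drop = FALSE])
    if (any(f0[, t] <= 0)) {
      bad <- which(f0[, t] <= 0)[1]
      .stop_field("F0", sprintf("non-positive baseline for ROI %d, trial %d",
                                bad, tr$trial_id[t]))
    }
    seg <- seq.int(seg_start[t], seg_end[t])
    dff[, seg] <- session$traces[, seg, drop = FALSE] / f0[, t] - 1
    # baseline sd of 1 s window means over the pre-onset ITI
    lo <- if (t == 1) max(0, on - tile_span) else
      max(tr$odour_onset[t - 1] + guard, on - tile_span)
    m <- floor(on - lo + 1e-9)
    if (m < 2) {
      .stop_field("baseline",
                  sprintf("trial %d: pre-onset period of %.2f s cannot hold 2 one-second windows",
                          tr$trial_id[t], on - lo))
    }
    wm <- vapply(seq_len(m), function(j) {
      wf <- window_frames(on - j, on - j + 1, fr, n_frames)
      rowMeans(session$traces[, wf, drop = FALSE] / f0[, t] - 1)
    }, numeric(n_rois))
    bsd[, t] <- apply(matrix(wm, nrow = n_rois), 1, stats::sd)
  }
  structure(list(dff = dff, f0 = f0, baseline_sd = bsd, trials = tr,
                 frame_rate = fr, animal_id = session$animal_id,
                 session_id = session$session_id),
            class = "dff_result")
}

#' Per-trial odour response amplitudes
#'
#' The response amplitude is the arithmetic mean of dF/F over the half-open
#' 1 s odour window `[onset, onset + response_window)` (30 frames at 30 Hz).
#' Trials whose window would be truncated by the end of the trace are dropped
#' with a warning rather than imputed.
#'
#' @param dff a `dff_result` from [compute_dff()].
#' @param response_window odour window length, seconds.
#' @return `n_rois x n_trials` matrix of amplitudes (dF/F); dropped trials are
#'   all-NA columns.
#' @export
response_amplitude <- function(dff, response_window = 1) {
  tr <- dff$trials
  fr <- dff$frame_rate
  n_frames <- ncol(dff$dff)
  amp <- matrix(NA_real_, nrow(dff$dff), nrow(tr))
  n_expected <- length(window_frames(0, response_window, fr))
  dropped <- integer(0)
  for (t in seq_len(nrow(tr))) {
    wf <- window_frames(tr$odour_onset[t], tr$odour_onset[t] + response_window,
                        fr, n_frames)
    if (length(wf) < n_expected) {
      dropped <- c(dropped, tr$trial_id[t])
      next
    }
    amp[, t] <- rowMeans(dff$dff[, wf, drop = FALSE])
  }
  if (length(dropped)) {
    warning(sprintf("dropped %d trial(s) with truncated odour windows: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  amp
}

#' Flag significant odour responses
#'
#' A response is significant when its magnitude strictly exceeds `threshold`
#' times the standard deviation of baseline fluctuations (the sd of baseline
#' 1 s window means, so noise and signal statistics are averaged identically).
#'
#' @param amplitude amplitude matrix from [response_amplitude()].
#' @param baseline_sd matching matrix of baseline sds (from [compute_dff()]).
#' @param threshold multiple of the baseline sd (default 3).
#' @return logical matrix of the same shape (NA where amplitude is NA).
#' @export
detect_significant_response <- function(amplitude, baseline_sd, threshold = 3) {
  if (!all(dim(amplitude) == dim(baseline_sd))) {
    stop("amplitude and baseline_sd dimensions differ", call. = FALSE)
  }
  if (any(!is.na(baseline_sd) & baseline_sd < 0)) {
    stop("baseline sd must be >= 0", call. = FALSE)
  }
  abs(amplitude) > threshold * baseline_sd
}

#' Build the per-(ROI, trial) response table of a session
#'
#' Convenience wrapper running [compute_dff()], [response_amplitude()] and
#' [detect_significant_response()] and joining the result with the trial
#' metadata in long format.
#'
#' @param session an `ob_session`.
#' @param equalize if TRUE, [equalize_fine_epochs()] is applied first.
#' @param baseline_window,tile_span,guard passed to [compute_dff()].
#' @param response_window passed to [response_amplitude()].
#' @param threshold passed to [detect_significant_response()].
#' @return data frame of class `response_table`, one row per (ROI, trial):
#'   identifiers, trial metadata, `amplitude`, `f0`, `baseline_sd`,
#'   `significant`.
#' @export
session_responses <- function(session, equalize = FALSE, baseline_window = 2,
                              tile_span = 10, guard = 3, response_window = 1,
                              threshold = 3) {
  if (equalize) session <- equalize_fine_epochs(session)
  d <- compute_dff(session, baseline_window, tile_span, guard)
  amp <- response_amplitude(d, response_window)
  sig <- detect_significant_response(amp, d$baseline_sd, threshold)
  tr <- d$trials
  n_rois <- nrow(amp)
  n_trials <- nrow(tr)
  res <- data.frame(
    animal_id = session$animal_id, session_id = session$session_id,
    roi = rep(seq_len(n_rois), times = n_trials),
    trial_id = rep(tr$trial_id, each = n_rois),
    epoch = rep(tr$epoch, each = n_rois),
    task = rep(tr$task, each = n_rois),
    odour = rep(tr$odour, each = n_rois),
    rewarded = rep(tr$rewarded, each = n_rois),
    probe = rep(tr$probe, each = n_rois),
    amplitude = as.vector(amp),
    f0 = as.vector(d$f0),
    baseline_sd = as.vector(d$baseline_sd),
    significant = as.vector(sig),
    stringsAsFactors = FALSE)
  res <- res[!is.na(res$amplitude), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("response_table", "data.frame")
  res
}

#' Response tables for a whole cohort
#'
#' @param cohort an `ob_cohort` (or list of `list(session = ...)`).
#' @param equalize equalize fine epochs per session first (default TRUE, the
#'   convention used by all task-contrast analyses).
#' @param ... passed to [session_responses()].
#' @return a `response_table` covering all sessions.
#' @export
cohort_responses <- function(cohort, equalize = TRUE, ...) {
  out <- do.call(rbind, lapply(cohort, function(el) {
    session_responses(el$session, equalize = equalize, ...)
  }))
  rownames(out) <- NULL
  class(out) <- c("response_table", "data.frame")
  out
}

#' Stimulus-selectivity t-score per ROI
#'
#' Compares each ROI's alpha vs alpha-prime response amplitudes during the
#' fine-discrimination epochs with a pooled-variance two-sample t-test
#' (two-tailed). The selectivity index is the absolute t-score; the preferred
#' odour follows its sign (t > 0: alpha). Used with a small number of trials,
#' which is why a t-score rather than a z-score is the selectivity currency.
#'
#' @param responses a `response_table` (fine epochs are selected internally;
#'   pass a table built from equalized sessions for the standard convention).
#' @param min_trials minimum trials required per odour (>= 2).
#' @return data frame of class `selectivity_result`, one row per ROI:
#'   `t`, `p`, `index` (= `|t|`), `preferred`, group sizes.
#' @export
selectivity_tscore <- function(responses, min_trials = 2) {
  min_trials <- max(2L, as.integer(min_trials))
  fine <- responses[responses$task == "fine" & !responses$probe &
                      responses$odour %in% c("alpha", "alphaprime"), ,
                    drop = FALSE]
  if (nrow(fine) == 0) stop("no fine-discrimination trials in responses",
                            call. = FALSE)
  out <- lapply(split(fine, list(fine$animal_id, fine$session_id, fine$roi),
                      drop = TRUE), function(d) {
    a <- d$amplitude[d$odour == "alpha"]
    ap <- d$amplitude[d$odour == "alphaprime"]
    if (length(a) < min_trials || length(ap) < min_trials) {
      stop(sprintf("ROI %d (%s/%s): needs >= %d trials per odour (got %d alpha, %d alpha')",
                   d$roi[1], d$animal_id[1], d$session_id[1], min_trials,
                   length(a), length(ap)), call. = FALSE)
    }
    tt <- .safe_ttest(a, ap)
    data.frame(animal_id = d$animal_id[1], session_id = d$session_id[1],
               roi = d$roi[1], n_alpha = length(a), n_alphaprime = length(ap),
               t = unname(tt$statistic), p = tt$p.value,
               index = abs(unname(tt$statistic)),
               preferred = if (unname(tt$statistic) > 0) "alpha" else "alphaprime",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$animal_id, res$session_id, res$roi), ]
  rownames(res) <- NULL
  class(res) <- c("selectivity_result", "data.frame")
  res
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf("Selectivity t-scores for %d ROIs: %d alpha-preferring, %d alpha'-preferring\n",
              nrow(x), sum(x$preferred == "alpha"),
              sum(x$preferred == "alphaprime")))
  cat(sprintf("  median selectivity index |t| = %.2f\n", stats::median(x$index)))
  invisible(x)
}
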