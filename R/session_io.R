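# Session container, on-disk format, validation, behaviour scoring and
# epoch equalization.

#' Construct a session object
#'
#' Bundles one behavioural/imaging session: the trial table, the ROI x frame
#' raw-fluorescence matrix, the respiration trace and acquisition metadata.
#' Validates all structural invariants (onsets strictly increasing and within
#' the trace, probe trials are rewarded alpha-prime coarse trials, matching
#' trace/sniff lengths).
#'
#' @param trials data frame with columns `trial_id`, `epoch`, `task`, `odour`,
#'   `rewarded`, `probe`, `odour_onset`, `outcome` and a list column
#'   `lick_times` (seconds from session start).
#' @param traces numeric matrix `n_rois x n_frames`, raw fluorescence.
#' @param sniff numeric vector of length `n_frames`.
#' @param frame_rate acquisition rate, Hz.
#' @param animal_id,session_id identifiers.
#' @return object of class `ob_session`.
#' @export
new_ob_session <- function(trials, traces, sniff, frame_rate,
                           animal_id = "a1", session_id = "s1") {
  s <- structure(list(trials = trials, traces = traces, sniff = sniff,
                      frame_rate = frame_rate,
                      animal_id = animal_id, session_id = session_id),
                 class = "ob_session")
  validate_session(s)
  s
}

#' Validate a session's structural invariants
#'
#' @param session an `ob_session`.
#' @return the session, invisibly; errors name the offending field.
#' @export
validate_session <- function(session) {
  s <- session
  if (!is.matrix(s$traces) || !is.numeric(s$traces)) {
    .stop_field("traces", "must be a numeric matrix")
  }
  if (nrow(s$traces) < 1) .stop_field("traces", "needs at least one ROI")
  if (!is.numeric(s$frame_rate) || s$frame_rate <= 0) {
    .stop_field("frame_rate", "must be > 0")
  }
  if (length(s$sniff) != ncol(s$traces)) {
    .stop_field("sniff", sprintf("length %d does not match %d trace frames",
                                 length(s$sniff), ncol(s$traces)))
  }
  tr <- s$trials
  need <- c("trial_id", "epoch", "task", "odour", "rewarded", "probe",
            "odour_onset", "outcome", "lick_times")
  miss <- setdiff(need, names(tr))
  if (length(miss)) .stop_field("trials", paste("missing column(s):",
                                                paste(miss, collapse = ", ")))
  if (nrow(tr) > 0) {
    if (any(diff(tr$odour_onset) <= 0)) {
      .stop_field("odour_onset", "must be strictly increasing across trials")
    }
    last_frame <- floor(max(tr$odour_onset) * s$frame_rate) + 1
    if (last_frame > ncol(s$traces)) {
      .stop_field("odour_onset",
                  sprintf("onset at %.3f s maps beyond the %d-frame trace",
                          max(tr$odour_onset), ncol(s$traces)))
    }
    bad <- tr$probe & !(tr$epoch == "Coarse" & tr$odour == "alphaprime" &
                          tr$rewarded)
    if (any(bad)) {
      .stop_field("probe", "probe trials must be rewarded alpha-prime trials in the Coarse epoch")
    }
    if (!all(tr$epoch %in% EPOCHS)) .stop_field("epoch", "unknown epoch label")
  }
  invisible(session)
}

#' @export
print.ob_session <- function(x, ...) {
  cat(sprintf("Session %s/%s: %d ROIs x %d frames @ %g Hz, %d trials\n",
              x$animal_id, x$session_id, nrow(x$traces), ncol(x$traces),
              x$frame_rate, nrow(x$trials)))
  if (nrow(x$trials)) {
    tab <- table(x$trials$epoch)[EPOCHS]
    cat(sprintf("  trials per epoch: Fine1 %d / Coarse %d / Fine2 %d (%d probe)\n",
                tab[1], tab[2], tab[3], sum(x$trials$probe)))
  }
  invisible(x)
}

#' Write a session to disk
#'
#' One directory per session: `trials.csv` (lick times semicolon-joined, all
#' doubles printed with 17 significant digits so the round trip is exact),
#' `traces.bin` and `sniff.bin` (flat little-endian float64 containers, row
#' dimension in the metadata) and `meta.yaml`. Optionally writes
#' `ground_truth.csv`.
#'
#' @param session an `ob_session`.
#' @param path directory to create/overwrite.
#' @param ground_truth optional [generate_ground_truth()] table.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, ground_truth = NULL) {
  validate_session(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tr <- session$trials
  out <- data.frame(
    trial_id = tr$trial_id, epoch = tr$epoch, task = tr$task,
    odour = tr$odour, rewarded = tr$rewarded, probe = tr$probe,
    odour_onset = .num_chr(tr$odour_onset), outcome = tr$outcome,
    lick_times = vapply(tr$lick_times, function(l)
      paste(.num_chr(l), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  utils::write.csv(out, file.path(path, "trials.csv"), row.names = FALSE)
  con <- file(file.path(path, "traces.bin"), "wb")
  writeBin(as.vector(session$traces), con, size = 8, endian = "little")
  close(con)
  con <- file(file.path(path, "sniff.bin"), "wb")
  writeBin(as.vector(session$sniff), con, size = 8, endian = "little")
  close(con)
  yaml::write_yaml(list(animal_id = session$animal_id,
                        session_id = session$session_id,
                        frame_rate = .num_chr(session$frame_rate),
                        n_rois = nrow(session$traces),
                        n_frames = ncol(session$traces)),
                   file.path(path, "meta.yaml"))
  if (!is.null(ground_truth)) {
    gt <- ground_truth
    for (cl in c("amp_alpha", "amp_alphaprime", "amp_beta", "delta")) {
      gt[[cl]] <- .num_chr(gt[[cl]])
    }
    utils::write.csv(gt, file.path(path, "ground_truth.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a session from disk
#'
#' Inverse of [write_session()]; the round trip is lossless (traces bit-exact,
#' trial fields value-exact). Validation errors name the offending field.
#'
#' @param path session directory.
#' @return an `ob_session`.
#' @export
read_session <- function(path) {
  for (f in c("trials.csv", "traces.bin", "sniff.bin", "meta.yaml")) {
    if (!file.exists(file.path(path, f))) {
      .stop_field(f, sprintf("missing from session directory %s", path))
    }
  }
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  for (f in c("animal_id", "session_id", "frame_rate", "n_rois", "n_frames")) {
    if (is.null(meta[[f]])) .stop_field(paste0("meta.yaml:", f), "missing")
  }
  n_rois <- as.integer(meta$n_rois)
  n_frames <- as.integer(meta$n_frames)
  con <- file(file.path(path, "traces.bin"), "rb")
  vals <- readBin(con, "double", n = n_rois * n_frames + 1L, size = 8,
                  endian = "little")
  close(con)
  if (length(vals) != n_rois * n_frames) {
    .stop_field("traces.bin", sprintf("holds %d values, expected %d x %d",
                                      length(vals), n_rois, n_frames))
  }
  traces <- matrix(vals, n_rois, n_frames)
  con <- file(file.path(path, "sniff.bin"), "rb")
  sniff <- readBin(con, "double", n = n_frames + 1L, size = 8,
                   endian = "little")
  close(con)
  if (length(sniff) != n_frames) {
    .stop_field("sniff.bin", sprintf("holds %d values, expected %d",
                                     length(sniff), n_frames))
  }
  raw <- utils::read.csv(file.path(path, "trials.csv"),
                         colClasses = c(lick_times = "character",
                                        odour_onset = "character"),
                         stringsAsFactors = FALSE)
  trials <- data.frame(trial_id = as.integer(raw$trial_id), epoch = raw$epoch,
                       task = raw$task, odour = raw$odour,
                       rewarded = as.logical(raw$rewarded),
                       probe = as.logical(raw$probe),
                       odour_onset = as.numeric(raw$odour_onset),
                       outcome = raw$outcome, stringsAsFactors = FALSE)
  trials$lick_times <- I(lapply(raw$lick_times, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0) else
      as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  }))
  new_ob_session(trials = trials, traces = traces, sniff = sniff,
                 frame_rate = as.numeric(meta$frame_rate),
                 animal_id = meta$animal_id, session_id = meta$session_id)
}

#' Write a cohort to a directory tree
#'
#' @param cohort an `ob_cohort`.
#' @param path output directory; one subdirectory per session.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  for (el in cohort) {
    write_session(el$session,
                  file.path(path, paste0(el$session$animal_id, "_",
                                         el$session$session_id)),
                  ground_truth = el$ground_truth)
  }
  invisible(path)
}

#' Read a cohort directory tree
#'
#' @param path directory holding session subdirectories.
#' @return an `ob_cohort` (ground truth attached where present on disk).
#' @export
read_cohort <- function(path) {
  dirs <- sort(list.dirs(path, recursive = FALSE))
  if (!length(dirs)) stop("no session directories under ", path, call. = FALSE)
  cohort <- lapply(dirs, function(d) {
    gt_file <- file.path(d, "ground_truth.csv")
    gt <- NULL
    if (file.exists(gt_file)) {
      raw <- utils::read.csv(gt_file, colClasses = c(
        amp_alpha = "character", amp_alphaprime = "character",
        amp_beta = "character", delta = "character"),
        stringsAsFactors = FALSE)
      gt <- data.frame(roi = as.integer(raw$roi),
                       selectivity_class = raw$selectivity_class,
                       amp_alpha = as.numeric(raw$amp_alpha),
                       amp_alphaprime = as.numeric(raw$amp_alphaprime),
                       amp_beta = as.numeric(raw$amp_beta),
                       modulated = as.logical(raw$modulated),
                       delta = as.numeric(raw$delta),
                       stringsAsFactors = FALSE)
      class(gt) <- c("ground_truth", "data.frame")
    }
    list(session = read_session(d), ground_truth = gt)
  })
  class(cohort) <- "ob_cohort"
  cohort
}

#' Score go/no-go behaviour of a session
#'
#' A rewarded (S+) trial is correct when at least one lick falls in the
#' response window `[onset + 1, onset + 2.5)` s; a non-rewarded (S-) trial is
#' correct when no lick falls in that window. Performance is the percentage
#' of correct trials. (The reward itself was available for 2 s from odour
#' onset; scoring follows the 1-2.5 s analysis window, a deliberate, documented
#' distinction.)
#'
#' @param session an `ob_session` with at least one trial.
#' @param window response window relative to odour onset, seconds (half-open).
#' @return object of class `behaviour_report`: `percent_correct` plus a
#'   per-trial outcome table.
#' @export
score_behaviour <- function(session, window = c(1, 2.5)) {
  tr <- session$trials
  if (nrow(tr) == 0) stop("session has no trials to score", call. = FALSE)
  licked <- mapply(function(licks, onset) {
    any(licks >= onset + window[1] & licks < onset + window[2])
  }, tr$lick_times, tr$odour_onset)
  correct <- ifelse(tr$rewarded, licked, !licked)
  rep <- list(percent_correct = 100 * mean(correct),
              trials = data.frame(trial_id = tr$trial_id, epoch = tr$epoch,
                                  task = tr$task, rewarded = tr$rewarded,
                                  licked = licked, correct = correct,
                                  stringsAsFactors = FALSE),
              animal_id = session$animal_id, session_id = session$session_id)
  class(rep) <- "behaviour_report"
  rep
}

#' @export
print.behaviour_report <- function(x, ...) {
  cat(sprintf("Behaviour %s/%s: %.1f%% correct over %d trials\n",
              x$animal_id, x$session_id, x$percent_correct, nrow(x$trials)))
  invisible(x)
}

#' Switch-aligned behavioural accuracy curve
#'
#' Accuracy per trial index relative to the two task switches (Fine1 -> Coarse
#' and Coarse -> Fine2), averaged across sessions. Index 0 is the first trial
#' after the switch; negative indices precede it. Each session contributes one
#' 0/1 outcome per index; the curve reports mean and s.e.m. (sd / sqrt(n))
#' across sessions at indices with at least one observation.
#'
#' @param sessions list of `ob_session` objects (or an `ob_cohort`).
#' @param span number of trials kept on each side of a switch.
#' @return data frame of class `switching_curve`: `alignment`, `rel_index`,
#'   `mean`, `sem`, `n`.
#' @export
switching_curve <- function(sessions, span = 8) {
  if (inherits(sessions, "ob_cohort")) {
    sessions <- lapply(sessions, `[[`, "session")
  }
  if (inherits(sessions, "ob_session")) sessions <- list(sessions)
  rows <- list()
  found_switch <- FALSE
  for (s in sessions) {
    rep <- score_behaviour(s)
    tr <- rep$trials
    for (alignment in c("fine_to_coarse", "coarse_to_fine")) {
      post_epoch <- if (alignment == "fine_to_coarse") "Coarse" else "Fine2"
      first_post <- match(post_epoch, tr$epoch)
      if (is.na(first_post)) next
      found_switch <- TRUE
      rel <- seq_len(nrow(tr)) - first_post
      keep <- rel >= -span & rel < span
      rows[[length(rows) + 1L]] <- data.frame(
        alignment = alignment, rel_index = rel[keep],
        correct = as.numeric(tr$correct[keep]), stringsAsFactors = FALSE)
    }
  }
  if (!found_switch) stop("no task switches found in the supplied sessions",
                          call. = FALSE)
  all <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(all, list(all$alignment, all$rel_index),
                                     drop = TRUE), function(d) {
    data.frame(alignment = d$alignment[1], rel_index = d$rel_index[1],
               mean = mean(d$correct),
               sem = if (nrow(d) > 1) .sem(d$correct) else NA_real_,
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$alignment, agg$rel_index), ]
  rownames(agg) <- NULL
  class(agg) <- c("switching_curve", "data.frame")
  agg
}

#' Equalize the two fine-discrimination epochs
#'
#' Returns a view of the session in which the Fine2 epoch is truncated from
#' its end so it holds the same number of trials as Fine1 (balancing
#' time-dependent effects such as bleaching). Fine1 and Coarse are untouched;
#' retained trials are unaltered. If Fine2 is already the shorter epoch both
#' epochs are kept whole with a warning.
#'
#' @param session an `ob_session` containing both fine epochs.
#' @return an `ob_session` with a filtered trial table (traces untouched).
#' @export
equalize_fine_epochs <- function(session) {
  tr <- session$trials
  n1 <- sum(tr$epoch == "Fine1")
  n2 <- sum(tr$epoch == "Fine2")
  if (n1 == 0 || n2 == 0) {
    stop("session must contain both Fine1 and Fine2 epochs", call. = FALSE)
  }
  if (n2 > n1) {
    fine2 <- which(tr$epoch == "Fine2")
    drop <- fine2[(n1 + 1):n2]
    session$trials <- tr[-drop, , drop = FALSE]
    rownames(session$trials) <- NULL
  } else if (n2 < n1) {
    warning(sprintf("Fine2 (%d trials) is shorter than Fine1 (%d); keeping both whole",
                    n2, n1), call. = FALSE)
  }
  session
}
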