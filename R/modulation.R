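# Per-ROI task-modulation testing: fine vs coarse alpha responses, shuffle
# calibration, sniff-confound regression, and the switch-aligned time course.

# Subset a response table to the alpha S+ pool used by every task contrast:
# rewarded alpha trials, probes excluded (probes are rewarded alpha-prime).
.alpha_pool <- function(responses) {
  responses[responses$odour == "alpha" & responses$rewarded &
              !responses$probe, , drop = FALSE]
}

# Vectorized pooled-variance two-sample t over the rows of A (ROIs x trials),
# groups given by logical g (TRUE = group 1). Equivalent to
# t.test(..., var.equal = TRUE) row by row; used where thousands of tests run
# inside the shuffle loop.
.row_ttest <- function(A, g) {
  n1 <- sum(g); n2 <- sum(!g)
  x1 <- A[, g, drop = FALSE]; x2 <- A[, !g, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df,
       mean1 = m1, mean2 = m2, n1 = n1, n2 = n2)
}

#' Per-ROI task-modulation t-test
#'
#' For every ROI, compares alpha-odour (S+) response amplitudes between the
#' fine-discrimination epochs (Fine1 + Fine2, which should come from an
#' epoch-equalized session) and the coarse epoch with a two-tailed
#' pooled-variance two-sample t-test. Probe trials never enter the alpha
#' pool. An ROI is called modulated when `p < alpha_level`.
#'
#' @param responses a `response_table` (typically from
#'   `cohort_responses(cohort, equalize = TRUE)`).
#' @param alpha_level nominal two-tailed significance level (default 0.05).
#' @param variant label stored in the result (`"raw"` or
#'   `"sniff_residualized"`).
#' @param min_trials minimum alpha S+ trials per task (>= 2).
#' @return data frame of class `modulation_result`, one row per ROI:
#'   `t_task`, `p_task`, `modulated`, `mean_fine_alpha`, `mean_coarse_alpha`,
#'   `delta` (fine - coarse), group sizes and the `variant`.
#' @export
task_modulation_test <- function(responses, alpha_level = 0.05,
                                 variant = "raw", min_trials = 2) {
  min_trials <- max(2L, as.integer(min_trials))
  pool <- .alpha_pool(responses)
  if (nrow(pool) == 0) stop("no rewarded alpha trials in responses",
                            call. = FALSE)
  out <- lapply(split(pool, list(pool$animal_id, pool$session_id, pool$roi),
                      drop = TRUE), function(d) {
    fine <- d$amplitude[d$task == "fine"]
    coarse <- d$amplitude[d$task == "coarse"]
    if (length(fine) < min_trials || length(coarse) < min_trials) {
      stop(sprintf("ROI %d (%s/%s): needs >= %d alpha S+ trials per task (got %d fine, %d coarse)",
                   d$roi[1], d$animal_id[1], d$session_id[1], min_trials,
                   length(fine), length(coarse)), call. = FALSE)
    }
    tt <- .safe_ttest(fine, coarse)
    data.frame(animal_id = d$animal_id[1], session_id = d$session_id[1],
               roi = d$roi[1], n_fine = length(fine), n_coarse = length(coarse),
               t_task = unname(tt$statistic), p_task = tt$p.value,
               modulated = tt$p.value < alpha_level,
               mean_fine_alpha = mean(fine), mean_coarse_alpha = mean(coarse),
               delta = mean(fine) - mean(coarse),
               variant = variant, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$animal_id, res$session_id, res$roi), ]
  rownames(res) <- NULL
  attr(res, "alpha_level") <- alpha_level
  class(res) <- c("modulation_result", "data.frame")
  res
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf("Task modulation (%s): %d/%d ROIs flagged at alpha = %g\n",
              x$variant[1], sum(x$modulated), nrow(x),
              attr(x, "alpha_level")))
  cat(sprintf("  mean fine - coarse alpha response: %+.3f dF/F (flagged ROIs: %+.3f)\n",
              mean(x$delta),
              if (any(x$modulated)) mean(x$delta[x$modulated]) else NA))
  invisible(x)
}

#' Shuffle control for the task-modulation test
#'
#' Calibrates the false-positive behaviour of [task_modulation_test()]: on
#' each shuffle, the fine/coarse task labels of every session's alpha S+
#' trials are randomly permuted (one permutation per session, shared by that
#' session's ROIs since they share the same trials), preserving group sizes,
#' and the per-ROI test is re-run. Reports the per-shuffle flagged counts and
#' their mean, which should sit near `alpha_level * n_rois`.
#'
#' @param responses a `response_table`.
#' @param alpha_level significance level of the per-ROI test.
#' @param n_shuffles number of label permutations (>= 1).
#' @param seed integer seed; permutations are reproducible.
#' @return object of class `shuffle_control`: `counts` (per shuffle),
#'   `mean_flagged`, `n_rois`, `alpha_level`, `n_shuffles`.
#' @export
shuffle_control <- function(responses, alpha_level = 0.05, n_shuffles = 100,
                            seed = 1) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1", call. = FALSE)
  pool <- .alpha_pool(responses)
  sessions <- split(pool, list(pool$animal_id, pool$session_id), drop = TRUE)
  # per session: amplitude matrix (ROI x trial) and true task labels
  mats <- lapply(sessions, function(d) {
    rois <- sort(unique(d$roi))
    trials <- unique(d[, c("trial_id", "task")])
    trials <- trials[order(trials$trial_id), ]
    A <- matrix(NA_real_, length(rois), nrow(trials),
                dimnames = list(rois, trials$trial_id))
    A[cbind(match(d$roi, rois), match(d$trial_id, trials$trial_id))] <-
      d$amplitude
    list(A = A, fine = trials$task == "fine")
  })
  n_rois <- sum(vapply(mats, function(m) nrow(m$A), 0))
  counts <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      flagged <- 0L
      for (m in mats) {
        g <- sample(m$fine)
        tt <- .row_ttest(m$A, g)
        flagged <- flagged + sum(tt$p < alpha_level)
      }
      flagged
    }, 0L)
  })
  structure(list(counts = counts, mean_flagged = mean(counts),
                 n_rois = n_rois, alpha_level = alpha_level,
                 n_shuffles = n_shuffles),
            class = "shuffle_control")
}

#' @export
print.shuffle_control <- function(x, ...) {
  cat(sprintf("Shuffle control: %.2f/%d ROIs flagged on average over %d permutations (nominal %.2f)\n",
              x$mean_flagged, x$n_rois, x$n_shuffles,
              x$alpha_level * x$n_rois))
  invisible(x)
}

#' Extract per-trial sniff features
#'
#' Detects inhalation onsets as negative-going zero crossings of the
#' mean-subtracted respiration trace (flow-sensor polarity is rig specific;
#' set `invert = TRUE` for the opposite convention) and summarizes each
#' odour window `[onset, onset + window)` by: inhalation count, sniff rate
#' (count / window) and first-inhalation latency after odour onset (NA when
#' no inhalation falls in the window). A flat or degenerate trace yields
#' all-NA features with a warning rather than fabricated values.
#'
#' @param sniff respiration trace (vector, one value per frame).
#' @param trials trial table with `trial_id` and `odour_onset`.
#' @param frame_rate Hz.
#' @param window odour window length, seconds.
#' @param invert flip the detected flow polarity.
#' @return data frame of class `sniff_features`: `trial_id`, `rate` (Hz),
#'   `latency` (s), `count`; plus attribute `onsets` (all detected onsets, s).
#' @export
extract_sniff_features <- function(sniff, trials, frame_rate, window = 1,
                                   invert = FALSE) {
  x <- sniff - mean(sniff)
  if (invert) x <- -x
  if (stats::sd(x) == 0) {
    warning("respiration trace is flat; sniff features flagged absent",
            call. = FALSE)
    out <- data.frame(trial_id = trials$trial_id, rate = NA_real_,
                      latency = NA_real_, count = NA_integer_)
    attr(out, "onsets") <- numeric(0)
    class(out) <- c("sniff_features", "data.frame")
    return(out)
  }
  cross <- which(x[-length(x)] >= 0 & x[-1] < 0)
  onsets <- cross / frame_rate  # time of the first sample below zero
  feats <- lapply(seq_len(nrow(trials)), function(i) {
    on <- trials$odour_onset[i]
    inw <- onsets[onsets >= on & onsets < on + window]
    data.frame(trial_id = trials$trial_id[i],
               rate = length(inw) / window,
               latency = if (length(inw)) inw[1] - on else NA_real_,
               count = length(inw))
  })
  out <- do.call(rbind, feats)
  attr(out, "onsets") <- onsets
  class(out) <- c("sniff_features", "data.frame")
  out
}

#' Regress sniff variability out of response amplitudes
#'
#' Per ROI, fits an ordinary-least-squares model of the alpha S+ response
#' amplitude on the sniff features (rate, first-inhalation latency,
#' inhalation count, plus intercept), pooling trials across tasks, and
#' replaces the amplitude by the residual. Features are shared by all ROIs of
#' a session, so the residual projection is computed once per session via a
#' QR decomposition. Missing latencies are mean-imputed (trial counts are
#' never changed); constant or collinear regressors are dropped with a
#' warning. Re-running [task_modulation_test()] on the result gives the
#' sniff-residualized modulation calls.
#'
#' The default regressors are sniff rate and first-inhalation latency; the
#' inhalation count is also available in the feature table but equals
#' `rate * window` at the default 1 s odour window, so supplying it too just
#' exercises the collinearity guard.
#'
#' @param responses a `response_table` (only the alpha S+ rows are
#'   residualized and returned).
#' @param features a `sniff_features` table per session, or a named list of
#'   them (names = `animal_id.session_id`) for multi-session tables; a single
#'   table is accepted when `responses` covers one session.
#' @param regressors character vector of feature columns to use.
#' @return a `response_table` of alpha S+ rows with residual amplitudes.
#' @export
residualize_on_sniff <- function(responses, features,
                                 regressors = c("rate", "latency")) {
  pool <- .alpha_pool(responses)
  keys <- unique(pool[, c("animal_id", "session_id")])
  single <- is.data.frame(features)
  if (single && nrow(keys) > 1) {
    stop("responses span several sessions; supply a named list of feature tables",
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(keys)), function(k) {
    d <- pool[pool$animal_id == keys$animal_id[k] &
                pool$session_id == keys$session_id[k], , drop = FALSE]
    ft <- if (single) features else
      features[[paste(keys$animal_id[k], keys$session_id[k], sep = ".")]]
    if (is.null(ft)) stop("missing sniff features for session ",
                          keys$session_id[k], call. = FALSE)
    trials <- sort(unique(d$trial_id))
    if (length(trials) < length(regressors) + 2) {
      stop(sprintf("session %s: %d trials cannot support %d regressors + intercept",
                   keys$session_id[k], length(trials), length(regressors)),
           call. = FALSE)
    }
    X <- as.matrix(ft[match(trials, ft$trial_id), regressors, drop = FALSE])
    for (j in seq_len(ncol(X))) {
      if (anyNA(X[, j])) X[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
    }
    keep <- apply(X, 2, function(col) stats::sd(col) > 0)
    if (!all(keep)) {
      warning(sprintf("dropping constant sniff regressor(s): %s",
                      paste(regressors[!keep], collapse = ", ")),
              call. = FALSE)
      X <- X[, keep, drop = FALSE]
    }
    X <- cbind(`(Intercept)` = 1, X)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      drop_cols <- qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]
      warning(sprintf("dropping collinear sniff regressor(s): %s",
                      paste(colnames(X)[drop_cols], collapse = ", ")),
              call. = FALSE)
      qrX <- qr(X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE])
    }
    rois <- sort(unique(d$roi))
    A <- matrix(NA_real_, length(trials), length(rois),
                dimnames = list(trials, rois))
    A[cbind(match(d$trial_id, trials), match(d$roi, rois))] <- d$amplitude
    R <- qr.resid(qrX, A)
    d$amplitude <- R[cbind(match(d$trial_id, trials), match(d$roi, rois))]
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("response_table", "data.frame")
  res
}

#' Per-session sniff features for a cohort
#'
#' @param cohort an `ob_cohort`.
#' @param ... passed to [extract_sniff_features()].
#' @return named list (`animal_id.session_id`) of `sniff_features` tables.
#' @export
cohort_sniff_features <- function(cohort, ...) {
  out <- lapply(cohort, function(el) {
    s <- el$session
    extract_sniff_features(s$sniff, s$trials, s$frame_rate, ...)
  })
  names(out) <- vapply(cohort, function(el)
    paste(el$session$animal_id, el$session$session_id, sep = "."), "")
  out
}

#' Switch-aligned time course of modulated-ROI responses
#'
#' For each modulated ROI, every alpha S+ amplitude is expressed relative to
#' that ROI's mean Fine1 alpha response, and the relative responses are
#' averaged across ROIs at each alpha-trial position within epoch (positions
#' count alpha S+ trials only). Also reports the first-coarse-trial change
#' (two-sample t of the position-1 coarse values against all Fine1 relative
#' values, across ROIs) and the first Fine2 position at which responses stop
#' differing from Fine1 (`p > alpha_level` position by position).
#'
#' @param responses a `response_table`.
#' @param modulated data frame with `animal_id`, `session_id`, `roi` rows
#'   selecting the ROI set (e.g. flagged rows of a `modulation_result`).
#' @param alpha_level level for the recovery criterion.
#' @return object of class `switching_timecourse`: `timecourse` (per epoch x
#'   position mean, sem, n), `first_coarse` (mean, sem, t, p, n), and
#'   `recovery_position` (NA when no position qualifies).
#' @export
switching_timecourse <- function(responses, modulated, alpha_level = 0.05) {
  if (nrow(modulated) == 0) stop("modulated ROI set is empty", call. = FALSE)
  pool <- .alpha_pool(responses)
  key <- paste(pool$animal_id, pool$session_id, pool$roi)
  sel <- key %in% paste(modulated$animal_id, modulated$session_id,
                        modulated$roi)
  pool <- pool[sel, , drop = FALSE]
  if (nrow(pool) == 0) stop("no responses for the modulated ROI set",
                            call. = FALSE)
  per_roi <- split(pool, paste(pool$animal_id, pool$session_id, pool$roi))
  rel <- do.call(rbind, lapply(per_roi, function(d) {
    d <- d[order(d$trial_id), ]
    base <- mean(d$amplitude[d$epoch == "Fine1"])
    d$rel <- d$amplitude - base
    d$position <- stats::ave(d$trial_id, d$epoch, FUN = seq_along)
    d
  }))
  tc <- do.call(rbind, lapply(split(rel, list(rel$epoch, rel$position),
                                    drop = TRUE), function(d) {
    data.frame(epoch = d$epoch[1], position = d$position[1],
               mean = mean(d$rel),
               sem = if (nrow(d) > 1) .sem(d$rel) else NA_real_,
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  tc <- tc[order(match(tc$epoch, EPOCHS), tc$position), ]
  rownames(tc) <- NULL
  fine1_rel <- rel$rel[rel$epoch == "Fine1"]
  pos_test <- function(epoch, position) {
    v <- rel$rel[rel$epoch == epoch & rel$position == position]
    if (length(v) < 2) return(NULL)
    tt <- .safe_ttest(v, fine1_rel)
    list(mean = mean(v), sem = .sem(v), t = unname(tt$statistic),
         p = tt$p.value, n = length(v))
  }
  first_coarse <- pos_test("Coarse", 1)
  fine2_pos <- sort(unique(rel$position[rel$epoch == "Fine2"]))
  recovery <- NA_integer_
  for (ps in fine2_pos) {
    res <- pos_test("Fine2", ps)
    if (!is.null(res) && res$p > alpha_level) { recovery <- ps; break }
  }
  structure(list(timecourse = tc, first_coarse = first_coarse,
                 recovery_position = recovery, alpha_level = alpha_level,
                 n_rois = length(per_roi)),
            class = "switching_timecourse")
}

#' @export
print.switching_timecourse <- function(x, ...) {
  cat(sprintf("Switch-aligned time course over %d modulated ROIs\n", x$n_rois))
  if (!is.null(x$first_coarse)) {
    cat(sprintf("  first coarse alpha trial: %+.3f +/- %.3f dF/F (t = %.2f, p = %.3g, n = %d)\n",
                x$first_coarse$mean, x$first_coarse$sem, x$first_coarse$t,
                x$first_coarse$p, x$first_coarse$n))
  }
  cat(sprintf("  Fine2 responses indistinguishable from Fine1 from alpha-trial position %s\n",
              ifelse(is.na(x$recovery_position), "NA",
                     x$recovery_position)))
  invisible(x)
}
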