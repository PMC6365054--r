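# Population-level analyses: pseudo-population transients, PCA trajectories,
# alpha/alpha' correlation and ROI-removal decorrelation, linear decoding,
# and selectivity enrichment among modulated ROIs.

#' Default pseudo-population conditions
#'
#' Condition = (odour, epoch set). The defaults separate the two fine epochs
#' for the alpha odour so reversibility (Fine1 vs Fine2) can be compared with
#' the task contrast (fine vs coarse), and add the alpha-prime fine condition.
#' Probe trials never enter a condition pool.
#'
#' @return named list of `list(odour, epochs)`.
#' @export
default_conditions <- function() {
  list(alpha.fine1 = list(odour = "alpha", epochs = "Fine1"),
       alpha.fine2 = list(odour = "alpha", epochs = "Fine2"),
       alpha.coarse = list(odour = "alpha", epochs = "Coarse"),
       alphaprime.fine = list(odour = "alphaprime",
                              epochs = c("Fine1", "Fine2")))
}

#' Build a pseudo-population of condition-averaged transients
#'
#' For every ROI pooled across sessions, the trial-averaged dF/F transient is
#' computed per condition over the peri-odour window and the condition blocks
#' are concatenated along time, yielding an
#' `n_rois x (n_conditions * n_timepoints)` matrix. ROIs missing any
#' requested condition are excluded with a warning.
#'
#' @param cohort an `ob_cohort`.
#' @param conditions a [default_conditions()]-style list.
#' @param window peri-odour window `c(start, end)` in seconds relative to
#'   odour onset (half-open).
#' @param equalize equalize fine epochs per session first.
#' @param baseline_window,tile_span,guard passed to [compute_dff()].
#' @return object of class `pseudo_population`: `mat`, `conditions` (label,
#'   first column, n_time), `provenance` (animal, session, roi per row),
#'   `time` (within-block timepoints, s), `frame_rate`.
#' @export
build_pseudopopulation <- function(cohort, conditions = default_conditions(),
                                   window = c(-1, 2), equalize = TRUE,
                                   baseline_window = 2, tile_span = 10,
                                   guard = 3) {
  stopifnot(length(window) == 2, window[2] > window[1])
  blocks <- list()
  prov <- list()
  n_time <- NULL
  for (el in cohort) {
    session <- el$session
    if (equalize) session <- equalize_fine_epochs(session)
    d <- compute_dff(session, baseline_window, tile_span, guard)
    fr <- session$frame_rate
    nt <- length(window_frames(0, window[2] - window[1], fr))
    if (is.null(n_time)) n_time <- nt
    if (nt != n_time) stop("sessions disagree on frame rate / window length",
                           call. = FALSE)
    tr <- session$trials
    n_rois <- nrow(session$traces)
    cond_means <- array(NA_real_, c(n_rois, n_time, length(conditions)))
    for (ci in seq_along(conditions)) {
      cn <- conditions[[ci]]
      use <- which(tr$odour == cn$odour & tr$epoch %in% cn$epochs & !tr$probe)
      if (!length(use)) next
      acc <- matrix(0, n_rois, n_time)
      n_ok <- 0L
      for (t in use) {
        wf <- window_frames(tr$odour_onset[t] + window[1],
                            tr$odour_onset[t] + window[2], fr,
                            ncol(d$dff))
        if (length(wf) != n_time) next
        acc <- acc + d$dff[, wf, drop = FALSE]
        n_ok <- n_ok + 1L
      }
      if (n_ok > 0) cond_means[, , ci] <- acc / n_ok
    }
    has_all <- apply(cond_means, 1, function(m) !anyNA(m))
    if (!all(has_all)) {
      warning(sprintf("%s/%s: excluding %d ROI(s) missing a condition",
                      session$animal_id, session$session_id, sum(!has_all)),
              call. = FALSE)
    }
    keep <- which(has_all)
    if (!length(keep)) next
    blk <- matrix(aperm(cond_means[keep, , , drop = FALSE], c(1, 2, 3)),
                  nrow = length(keep))
    blocks[[length(blocks) + 1L]] <- blk
    prov[[length(prov) + 1L]] <- data.frame(
      animal_id = session$animal_id, session_id = session$session_id,
      roi = keep, stringsAsFactors = FALSE)
  }
  mat <- do.call(rbind, blocks)
  cond_tab <- data.frame(label = names(conditions),
                         first_col = (seq_along(conditions) - 1L) * n_time + 1L,
                         n_time = n_time, stringsAsFactors = FALSE)
  structure(list(mat = mat, conditions = cond_tab,
                 provenance = do.call(rbind, prov),
                 time = window[1] + (seq_len(n_time) - 1) /
                   cohort[[1]]$session$frame_rate,
                 frame_rate = cohort[[1]]$session$frame_rate),
            class = "pseudo_population")
}

#' @export
print.pseudo_population <- function(x, ...) {
  cat(sprintf("Pseudo-population: %d ROIs x %d condition(s) x %d timepoints\n",
              nrow(x$mat), nrow(x$conditions), x$conditions$n_time[1]))
  invisible(x)
}

#' PCA trajectories of the pseudo-population
#'
#' Principal components are computed over the concatenated matrix with
#' time-condition columns as observations and ROIs as variables: each ROI's
#' mean over all concatenated timepoints is subtracted (no variance scaling,
#' so components stay in dF/F units) and the covariance across timepoints is
#' eigendecomposed ([stats::prcomp()]). Each condition's block of timepoints
#' is then projected onto the leading components to give its trajectory.
#' Component signs are fixed by making each component's largest-magnitude ROI
#' loading positive.
#'
#' @param pop a `pseudo_population`.
#' @param n_components number of components (default 3); when fewer ROIs are
#'   available, the available number is returned with a warning.
#' @return object of class `trajectory_set`: `trajectories` (long data frame:
#'   condition, time, pc1..pcK), `explained` (variance fractions, all
#'   components), `loadings` (ROIs x K), `n_components`.
#' @export
pca_trajectories <- function(pop, n_components = 3) {
  n_rois <- nrow(pop$mat)
  if (n_rois < 3) stop("need at least 3 ROIs for trajectory analysis",
                       call. = FALSE)
  k <- n_components
  if (n_rois < k) {
    warning(sprintf("only %d ROIs: returning %d component(s)", n_rois, n_rois),
            call. = FALSE)
    k <- n_rois
  }
  X <- t(pop$mat)  # observations = time-condition points, variables = ROIs
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  n_time <- pop$conditions$n_time[1]
  traj <- do.call(rbind, lapply(seq_len(nrow(pop$conditions)), function(ci) {
    cols <- pop$conditions$first_col[ci] + seq_len(n_time) - 1L
    out <- data.frame(condition = pop$conditions$label[ci], time = pop$time,
                      stringsAsFactors = FALSE)
    for (j in seq_len(k)) out[[paste0("pc", j)]] <- scores[cols, j]
    out
  }))
  rownames(traj) <- NULL
  structure(list(trajectories = traj, explained = expl, loadings = load,
                 n_components = k),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("PCA trajectories: %d condition(s), %d components (%.1f%% variance)\n",
              length(unique(x$trajectories$condition)), x$n_components,
              100 * sum(x$explained[seq_len(x$n_components)])))
  invisible(x)
}

#' @export
plot.trajectory_set <- function(x, pcs = c(1, 2), ...) {
  tr <- x$trajectories
  conds <- unique(tr$condition)
  cols <- grDevices::hcl.colors(max(3, length(conds)), "Dark 2")
  xs <- tr[[paste0("pc", pcs[1])]]
  ys <- tr[[paste0("pc", pcs[2])]]
  graphics::plot(range(xs), range(ys), type = "n",
                 xlab = sprintf("PC%d (dF/F)", pcs[1]),
                 ylab = sprintf("PC%d (dF/F)", pcs[2]), ...)
  for (i in seq_along(conds)) {
    sel <- tr$condition == conds[i]
    graphics::lines(xs[sel], ys[sel], col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = conds, col = cols[seq_along(conds)],
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}

#' Mean trajectory separation between two conditions
#'
#' Mean Euclidean distance between two conditions' leading-PC coordinates
#' over matching timepoints within `window` (default: the odour second).
#'
#' @param traj a `trajectory_set`.
#' @param cond_a,cond_b condition labels.
#' @param window time window (s, relative to odour onset) over which the
#'   distance is averaged.
#' @return mean distance (dF/F units in PC space).
#' @export
trajectory_separation <- function(traj, cond_a, cond_b, window = c(0, 1)) {
  tr <- traj$trajectories
  pcs <- paste0("pc", seq_len(traj$n_components))
  a <- tr[tr$condition == cond_a, , drop = FALSE]
  b <- tr[tr$condition == cond_b, , drop = FALSE]
  sel <- a$time >= window[1] & a$time < window[2]
  d <- sqrt(rowSums((as.matrix(a[sel, pcs]) - as.matrix(b[sel, pcs]))^2))
  mean(d)
}

# Per-group (animal) mean alpha / alpha-prime response vectors across ROIs.
.group_mean_vectors <- function(responses, group_by = c("animal", "session"),
                                epochs = c("Fine1", "Fine2")) {
  group_by <- match.arg(group_by)
  use <- responses[responses$epoch %in% epochs & !responses$probe &
                     responses$odour %in% c("alpha", "alphaprime"), ,
                   drop = FALSE]
  grp <- if (group_by == "animal") use$animal_id else
    paste(use$animal_id, use$session_id, sep = ".")
  lapply(split(use, grp), function(d) {
    key <- paste(d$animal_id, d$session_id, d$roi)
    rois <- unique(key[order(d$session_id, d$roi)])
    va <- tapply(d$amplitude[d$odour == "alpha"],
                 factor(key[d$odour == "alpha"], levels = rois), mean)
    vp <- tapply(d$amplitude[d$odour == "alphaprime"],
                 factor(key[d$odour == "alphaprime"], levels = rois), mean)
    list(alpha = as.numeric(va), alphaprime = as.numeric(vp), rois = rois)
  })
}

#' Correlation between alpha and alpha-prime population responses
#'
#' Per group (animal by default, matching the small per-location ROI counts;
#' per session/imaging-location via `group_by = "session"`), the per-ROI mean
#' alpha amplitudes and mean alpha-prime amplitudes over the selected epochs
#' are treated as two vectors and their Pearson correlation is computed.
#'
#' @param responses a `response_table`.
#' @param group_by `"animal"` or `"session"`.
#' @param epochs epochs whose trials enter the means (default: fine epochs,
#'   where both mixtures are presented repeatedly).
#' @return data frame: `group`, `r`, `n_rois`; zero-variance vectors give
#'   `r = NA` with a warning.
#' @export
response_correlation <- function(responses, group_by = "animal",
                                 epochs = c("Fine1", "Fine2")) {
  vecs <- .group_mean_vectors(responses, group_by, epochs)
  out <- do.call(rbind, lapply(names(vecs), function(g) {
    v <- vecs[[g]]
    if (length(v$alpha) < 3) stop(sprintf("group %s has < 3 ROIs", g),
                                  call. = FALSE)
    if (stats::sd(v$alpha) == 0 || stats::sd(v$alphaprime) == 0) {
      warning(sprintf("group %s: zero-variance response vector, r undefined", g),
              call. = FALSE)
      r <- NA_real_
    } else {
      r <- stats::cor(v$alpha, v$alphaprime)
    }
    data.frame(group = g, r = r, n_rois = length(v$alpha),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Correlation change after removing an ROI set
#'
#' Per group, recomputes the alpha/alpha-prime Pearson correlation after
#' removing the given ROI set and reports
#' `change = (r_removed - r_full) / r_full` (a fraction; positive change
#' means the representations became more correlated). A size-matched random
#' control repeats the removal with `n_random` random subsets per group.
#'
#' @param responses a `response_table`.
#' @param removal data frame with `animal_id`, `session_id`, `roi` rows (e.g.
#'   the flagged rows of a `modulation_result`); may be empty (change 0).
#' @param group_by `"animal"` or `"session"`.
#' @param epochs epochs entering the response means.
#' @param n_random random size-matched replicates per group.
#' @param seed integer seed for the random control.
#' @return object of class `correlation_change`: `per_group` (r_full,
#'   r_removed, change, n_removed), `random` (per replicate), and summary
#'   means (`mean_change`, `mean_random_change`, as fractions).
#' @export
removal_correlation_change <- function(responses, removal,
                                       group_by = "animal",
                                       epochs = c("Fine1", "Fine2"),
                                       n_random = 100, seed = 1) {
  vecs <- .group_mean_vectors(responses, group_by, epochs)
  rem_keys <- if (nrow(removal)) paste(removal$animal_id, removal$session_id,
                                       removal$roi) else character(0)
  per_group <- list()
  random <- list()
  with_seed(seed, {
    for (g in names(vecs)) {
      v <- vecs[[g]]
      in_rem <- v$rois %in% rem_keys
      if (all(in_rem)) stop(sprintf("group %s: removal set covers every ROI", g),
                            call. = FALSE)
      r_full <- stats::cor(v$alpha, v$alphaprime)
      r_rem <- if (any(in_rem)) {
        stats::cor(v$alpha[!in_rem], v$alphaprime[!in_rem])
      } else r_full
      per_group[[g]] <- data.frame(
        group = g, r_full = r_full, r_removed = r_rem,
        change = (r_rem - r_full) / r_full,
        n_removed = sum(in_rem), n_rois = length(v$rois),
        stringsAsFactors = FALSE)
      k <- sum(in_rem)
      if (k > 0 && n_random > 0) {
        ch <- vapply(seq_len(n_random), function(rep) {
          idx <- sample(length(v$rois), k)
          (stats::cor(v$alpha[-idx], v$alphaprime[-idx]) - r_full) / r_full
        }, 0)
        random[[g]] <- data.frame(group = g, replicate = seq_len(n_random),
                                  change = ch, stringsAsFactors = FALSE)
      }
    }
  })
  per_group <- do.call(rbind, per_group)
  random <- if (length(random)) do.call(rbind, random) else
    data.frame(group = character(0), replicate = integer(0),
               change = numeric(0))
  rownames(per_group) <- rownames(random) <- NULL
  structure(list(per_group = per_group, random = random,
                 mean_change = mean(per_group$change),
                 mean_random_change = if (nrow(random))
                   mean(tapply(random$change, random$group, mean)) else 0),
            class = "correlation_change")
}

#' @export
print.correlation_change <- function(x, ...) {
  cat(sprintf("alpha/alpha' correlation change over %d group(s):\n",
              nrow(x$per_group)))
  cat(sprintf("  removal set: mean change = %+.2f%%; size-matched random: %+.2f%%\n",
              100 * x$mean_change, 100 * x$mean_random_change))
  invisible(x)
}

# ---- shrinkage linear discriminant decoder ------------------------------

# Analytic shrinkage of the pooled within-class covariance toward its
# diagonal (Schafer-Strimmer): lambda* = sum Var(s_ij) / sum s_ij^2 over the
# off-diagonal entries, clipped to [0, 1]. Xc is the within-class-centered
# data matrix (n x p).
.shrinkage_lambda <- function(Xc, n_eff) {
  n <- nrow(Xc)
  S <- crossprod(Xc) / n_eff
  W2 <- crossprod(Xc^2)             # sum_k x_ki^2 x_kj^2
  varS <- (n / ((n_eff)^3)) * (W2 - (crossprod(Xc))^2 / n)
  off <- upper.tri(S) | lower.tri(S)
  denom <- sum(S[off]^2)
  if (denom <= 0) return(1)
  min(1, max(0, sum(varS[off]) / denom))
}

# Fit equal-prior LDA with diagonal-shrunk pooled covariance. X: n x p,
# y: factor with 2+ levels. lambda = NULL -> analytic.
.lda_fit <- function(X, y, lambda = NULL) {
  y <- factor(y)
  classes <- levels(y)
  mus <- t(vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                  numeric(ncol(X))))
  Xc <- X - mus[as.integer(y), , drop = FALSE]
  n_eff <- nrow(X) - length(classes)
  if (n_eff < 1) stop("too few trials to estimate the pooled covariance",
                      call. = FALSE)
  S <- crossprod(Xc) / n_eff
  if (is.null(lambda)) lambda <- .shrinkage_lambda(Xc, n_eff)
  Ssh <- (1 - lambda) * S + lambda * diag(diag(S), ncol(X))
  # guard against exactly zero variance features
  dg <- diag(Ssh)
  dg[dg <= 0] <- max(dg[dg > 0], 1e-12)
  diag(Ssh) <- dg
  list(means = mus, cov = Ssh, lambda = lambda, classes = classes)
}

.lda_predict <- function(fit, X) {
  # equal priors: delta_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2
  A <- solve(fit$cov, t(fit$means))            # p x K
  const <- -0.5 * colSums(t(fit$means) * A)    # K
  scores <- X %*% A + rep(const, each = nrow(X))
  fit$classes[max.col(scores, ties.method = "first")]
}

#' Train and evaluate a linear odour decoder
#'
#' Per session, a linear-discriminant classifier (equal priors, pooled
#' covariance shrunk analytically toward its diagonal — the trial count is
#' often smaller than the ROI count) is trained to label single trials as
#' S+ vs S- from the population amplitude vector, using a stratified 2/3
#' train / 1/3 test split, and scored as the percentage of correctly labelled
#' test trials. Splits are redrawn `n_repeats` times and accuracies averaged.
#'
#' Fine-task decoding uses the fine-epoch alpha vs alpha-prime trials; coarse
#' uses the coarse-epoch alpha (non-probe) vs beta trials.
#'
#' @param responses a `response_table`.
#' @param task `"fine"` or `"coarse"`.
#' @param roi_set label recorded in the report (`"all"`,
#'   `"modulated_removed"`, `"random_removed"`, ...).
#' @param exclude optional data frame (`animal_id`, `session_id`, `roi`) of
#'   ROIs removed before training.
#' @param split_seed integer seed for the splits.
#' @param n_repeats number of random splits averaged.
#' @param lambda shrinkage weight; NULL for the analytic choice.
#' @return object of class `decoder_report`: `per_session` (session,
#'   accuracy %, n_trials, n_rois), `accuracy` (mean %), `task`, `roi_set`.
#' @export
train_eval_decoder <- function(responses, task = c("fine", "coarse"),
                               roi_set = "all", exclude = NULL,
                               split_seed = 1, n_repeats = 100,
                               lambda = NULL) {
  task <- match.arg(task)
  use <- responses[responses$task == task & !responses$probe, , drop = FALSE]
  if (task == "coarse") {
    use <- use[use$odour %in% c("alpha", "beta"), , drop = FALSE]
  } else {
    use <- use[use$odour %in% c("alpha", "alphaprime"), , drop = FALSE]
  }
  if (!is.null(exclude) && nrow(exclude)) {
    key <- paste(use$animal_id, use$session_id, use$roi)
    use <- use[!(key %in% paste(exclude$animal_id, exclude$session_id,
                                exclude$roi)), , drop = FALSE]
  }
  sessions <- split(use, list(use$animal_id, use$session_id), drop = TRUE)
  per_session <- with_seed(split_seed, {
    do.call(rbind, lapply(names(sessions), function(sn) {
      d <- sessions[[sn]]
      trials <- unique(d[, c("trial_id", "rewarded")])
      trials <- trials[order(trials$trial_id), ]
      rois <- sort(unique(d$roi))
      X <- matrix(NA_real_, nrow(trials), length(rois))
      X[cbind(match(d$trial_id, trials$trial_id), match(d$roi, rois))] <-
        d$amplitude
      y <- factor(ifelse(trials$rewarded, "splus", "sminus"))
      if (min(table(y)) < 3) {
        stop(sprintf("session %s: need >= 3 trials per class", sn),
             call. = FALSE)
      }
      accs <- vapply(seq_len(n_repeats), function(rep) {
        test <- logical(nrow(X))
        for (cl in levels(y)) {
          idx <- which(y == cl)
          n_test <- max(1L, round(length(idx) / 3))
          test[sample(idx, n_test)] <- TRUE
        }
        fit <- .lda_fit(X[!test, , drop = FALSE], y[!test], lambda)
        pred <- .lda_predict(fit, X[test, , drop = FALSE])
        100 * mean(pred == as.character(y[test]))
      }, 0)
      data.frame(session = sn, accuracy = mean(accs),
                 n_trials = nrow(X), n_rois = length(rois),
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(per_session) <- NULL
  structure(list(per_session = per_session,
                 accuracy = mean(per_session$accuracy),
                 task = task, roi_set = roi_set, n_repeats = n_repeats),
            class = "decoder_report")
}

#' @export
print.decoder_report <- function(x, ...) {
  cat(sprintf("%s-task decoder (%s): %.1f%% accuracy (mean over %d sessions x %d splits)\n",
              x$task, x$roi_set, x$accuracy, nrow(x$per_session), x$n_repeats))
  invisible(x)
}

#' Selectivity enrichment among task-modulated ROIs
#'
#' Compares the distribution of selectivity indices (|t|) between modulated
#' and non-modulated ROIs with a two-sample Kolmogorov-Smirnov test, and
#' reports the fraction of stimulus-selective ROIs (selectivity p below
#' `selective_alpha`) that are modulated against the overall modulated
#' fraction.
#'
#' @param selectivity a `selectivity_result`.
#' @param modulation a `modulation_result` over the same ROIs.
#' @param selective_alpha level defining "stimulus selective".
#' @return object of class `selectivity_enrichment`: `ks_stat`, `ks_p`,
#'   group sizes, `frac_selective_modulated`, `frac_modulated`.
#' @export
selectivity_enrichment <- function(selectivity, modulation,
                                   selective_alpha = 0.05) {
  key_s <- paste(selectivity$animal_id, selectivity$session_id,
                 selectivity$roi)
  key_m <- paste(modulation$animal_id, modulation$session_id, modulation$roi)
  ord <- match(key_s, key_m)
  if (anyNA(ord)) stop("selectivity and modulation tables cover different ROIs",
                       call. = FALSE)
  mod <- modulation$modulated[ord]
  x <- selectivity$index[mod]
  y <- selectivity$index[!mod]
  if (!length(x) || !length(y)) stop("one enrichment group is empty",
                                     call. = FALSE)
  ks <- suppressWarnings(stats::ks.test(x, y))
  selective <- selectivity$p < selective_alpha
  structure(list(ks_stat = unname(ks$statistic), ks_p = ks$p.value,
                 n_modulated = length(x), n_non_modulated = length(y),
                 frac_selective_modulated = mean(mod[selective]),
                 frac_modulated = mean(mod),
                 n_selective = sum(selective)),
            class = "selectivity_enrichment")
}

#' @export
print.selectivity_enrichment <- function(x, ...) {
  cat(sprintf("Selectivity enrichment: KS = %.2f (p = %.3g), %d modulated vs %d non-modulated ROIs\n",
              x$ks_stat, x$ks_p, x$n_modulated, x$n_non_modulated))
  cat(sprintf("  %.0f%% of selective ROIs modulated vs %.0f%% overall\n",
              100 * x$frac_selective_modulated, 100 * x$frac_modulated))
  invisible(x)
}
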