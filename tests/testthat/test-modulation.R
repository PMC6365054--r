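# Task-modulation testing, shuffle calibration, sniff features and
# regression, switch-aligned time course.

alpha_pool_table <- function(fine_vals, coarse_vals, roi = 1) {
  nf <- length(fine_vals); nc <- length(coarse_vals)
  make_response_table(
    roi = roi, trial_id = seq_len(nf + nc),
    epoch = c(rep(c("Fine1", "Fine2"), length.out = nf), rep("Coarse", nc)),
    task = c(rep("fine", nf), rep("coarse", nc)),
    odour = "alpha", rewarded = TRUE,
    amplitude = c(fine_vals, coarse_vals))
}

test_that("task-modulation t and p match the closed-form oracle", {
  fine <- c(0.62, 0.55, 0.71, 0.66, 0.58)
  coarse <- c(0.41, 0.52, 0.44, 0.39)
  res <- task_modulation_test(alpha_pool_table(fine, coarse))
  sp2 <- ((4) * var(fine) + (3) * var(coarse)) / 7
  t_or <- (mean(fine) - mean(coarse)) / sqrt(sp2 * (1 / 5 + 1 / 4))
  p_or <- 2 * stats::pt(-abs(t_or), 7)
  expect_lt(abs(res$t_task - t_or), 1e-10)
  expect_lt(abs(res$p_task - p_or), 1e-10)
  expect_equal(res$delta, mean(fine) - mean(coarse))
  expect_equal(res$mean_fine_alpha - res$mean_coarse_alpha, res$delta)
  expect_true(res$modulated == (p_or < 0.05))
})

test_that("identical fine and coarse distributions are not called modulated", {
  v <- c(0.2, 0.3, 0.4, 0.5)
  res <- task_modulation_test(alpha_pool_table(v, v))
  expect_equal(res$t_task, 0)
  expect_false(res$modulated)
  # probe trials are never part of the alpha pool
  rt <- alpha_pool_table(v, v)
  probe_row <- rt[1, ]
  probe_row$trial_id <- 99L; probe_row$epoch <- "Coarse"
  probe_row$task <- "coarse"; probe_row$odour <- "alphaprime"
  probe_row$probe <- TRUE; probe_row$amplitude <- 5
  res2 <- task_modulation_test(rbind(rt, probe_row))
  expect_equal(res2$n_coarse, res$n_coarse)
  expect_error(task_modulation_test(alpha_pool_table(v, 0.3)), ">= 2")
})

test_that("the vectorized row t-test agrees with t.test", {
  set.seed(9)
  A <- matrix(rnorm(200), 10, 20)
  g <- rep(c(TRUE, FALSE), c(12, 8))
  rtt <- bulbswitch:::.row_ttest(A, g)
  for (i in 1:10) {
    tt <- stats::t.test(A[i, g], A[i, !g], var.equal = TRUE)
    expect_lt(abs(rtt$t[i] - unname(tt$statistic)), 1e-12)
    expect_lt(abs(rtt$p[i] - tt$p.value), 1e-12)
  }
})

test_that("shuffle control preserves group sizes, is seeded, and is calibrated", {
  coh <- generate_cohort(tiny_config(n_animals = 2, rois_per_animal = 25,
                                     epoch_lengths = c(12, 12, 12)), seed = 6)
  rt <- cohort_responses(coh, equalize = TRUE)
  s1 <- shuffle_control(rt, n_shuffles = 10, seed = 3)
  s2 <- shuffle_control(rt, n_shuffles = 10, seed = 3)
  expect_identical(s1$counts, s2$counts)
  expect_false(identical(s1$counts,
                         shuffle_control(rt, n_shuffles = 10, seed = 4)$counts))
  expect_equal(s1$n_rois, 50)

  # mean flagged count approximates alpha * n_rois (binomial null oracle)
  s3 <- shuffle_control(rt, alpha_level = 0.05, n_shuffles = 200, seed = 5)
  band <- 3 * sqrt(50 * 0.05 * 0.95 / 200) + 0.8  # sampling + test granularity
  expect_lt(abs(s3$mean_flagged - 0.05 * 50), band)
  expect_error(shuffle_control(rt, n_shuffles = 0), "n_shuffles")
})

test_that("sniff features recover rate, count, latency and true onsets", {
  cfg <- synth_config(sniff_rate_sd = 0)
  sn <- generate_sniff_trace(cfg, duration = 30, seed = 2)
  trials <- data.frame(trial_id = 1:2, odour_onset = c(10, 20))
  ft <- extract_sniff_features(sn$trace, trials, cfg$frame_rate)
  expect_equal(ft$rate, c(4, 4))
  expect_equal(ft$count, c(4L, 4L))
  expect_true(all(ft$latency >= 0 & ft$latency <= 0.25 + 1 / 30))

  # detected onsets match ground truth within one sample
  det <- attr(ft, "onsets")
  cfg2 <- synth_config(sniff_rate_sd = 0.5)
  sn2 <- generate_sniff_trace(cfg2, duration = 30, seed = 8)
  ft2 <- extract_sniff_features(sn2$trace, trials, cfg2$frame_rate)
  det2 <- attr(ft2, "onsets")
  # match each true onset (away from the edges) to the closest detection
  true2 <- sn2$onsets[sn2$onsets > 0.5 & sn2$onsets < 29.5]
  gap <- vapply(true2, function(o) min(abs(det2 - o)), 0)
  expect_lt(max(gap), 1.5 / cfg2$frame_rate)

  # flat trace -> features flagged absent with a warning
  expect_warning(ft3 <- extract_sniff_features(rep(1, 900), trials, 30),
                 "flat")
  expect_true(all(is.na(ft3$rate)))

  # no inhalation inside a (short) window -> latency absent
  slow <- generate_sniff_trace(synth_config(sniff_rate_mean = 1,
                                            sniff_rate_sd = 0), 30, seed = 1)
  t_no <- data.frame(trial_id = 1L, odour_onset = 10.4)
  ft4 <- extract_sniff_features(slow$trace, t_no, 30, window = 0.3)
  expect_true(is.na(ft4$latency))
  expect_equal(ft4$count, 0L)
})

test_that("sniff residualization reproduces least-squares structure exactly", {
  set.seed(12)
  n <- 24
  rate <- rnorm(n, 4, 1)
  lat <- runif(n, 0, 0.25)
  ft <- data.frame(trial_id = 1:n, rate = rate, latency = lat,
                   count = rate)
  # amplitudes exactly linear in rate -> residuals ~ 0
  rt_lin <- make_response_table(
    roi = 1, trial_id = 1:n,
    epoch = rep(c("Fine1", "Coarse", "Fine2"), each = 8),
    task = rep(c("fine", "coarse", "fine"), each = 8),
    odour = "alpha", rewarded = TRUE,
    amplitude = 0.3 + 0.05 * rate)
  res_lin <- residualize_on_sniff(rt_lin, ft)
  expect_lt(max(abs(res_lin$amplitude)), 1e-9)
  expect_equal(nrow(res_lin), nrow(rt_lin))  # trial count preserved

  # generic amplitudes: residuals orthogonal to centered regressors
  rt2 <- rt_lin
  rt2$amplitude <- rnorm(n, 0.4, 0.1)
  res2 <- residualize_on_sniff(rt2, ft)
  r <- res2$amplitude[order(res2$trial_id)]
  expect_lt(abs(sum(r * (rate - mean(rate)))), 1e-8)
  expect_lt(abs(sum(r * (lat - mean(lat)))), 1e-8)
  expect_lt(abs(sum(r)), 1e-8)

  # constant features -> intercept-only fit: residuals are demeaned amplitudes
  ft_const <- data.frame(trial_id = 1:n, rate = 4, latency = 0.1, count = 4)
  expect_warning(res3 <- residualize_on_sniff(rt2, ft_const), "constant")
  expect_equal(res3$amplitude[order(res3$trial_id)],
               rt2$amplitude - mean(rt2$amplitude))

  # collinear regressor (count = rate at 1 s window) dropped with a warning
  expect_warning(
    res4 <- residualize_on_sniff(rt2, ft,
                                 regressors = c("rate", "latency", "count")),
    "collinear")
  expect_equal(sort(res4$amplitude), sort(res2$amplitude))
})

test_that("residualization recovers modulation power under strong sniff coupling", {
  # strong-coupling regime with a large modulated class so the power
  # comparison is well resolved
  cfg <- synth_config(n_animals = 2, rois_per_animal = 50,
                      sniff_coupling = 0.3, frac_modulated = 0.3,
                      frac_alpha_selective = 0.5)
  coh <- generate_cohort(cfg, seed = 7)
  rt <- suppressWarnings(cohort_responses(coh, equalize = TRUE))
  raw <- task_modulation_test(rt)
  resid <- residualize_on_sniff(rt, cohort_sniff_features(coh))
  res <- task_modulation_test(resid, variant = "sniff_residualized")
  expect_gte(sum(res$modulated), sum(raw$modulated))
  # the gain comes from truly modulated ROIs
  key <- paste(raw$animal_id, raw$roi)
  gt_mod <- unlist(lapply(coh, function(el) el$ground_truth$modulated))
  names(gt_mod) <- unlist(lapply(coh, function(el)
    paste(el$session$animal_id, el$ground_truth$roi)))
  sens_raw <- mean(raw$modulated[gt_mod[key]])
  sens_res <- mean(res$modulated[gt_mod[paste(res$animal_id, res$roi)]])
  expect_gt(sens_res, sens_raw)
})

test_that("switch-aligned time course reports construction-exact changes", {
  # noiseless step: fine amplitude a, coarse amplitude a - d
  d <- 0.17
  rois <- 1:5
  rt <- do.call(rbind, lapply(rois, function(r)
    alpha_pool_table(rep(0.5 + 0.01 * r, 6), rep(0.5 + 0.01 * r - d, 4),
                     roi = r)))
  class(rt) <- c("response_table", "data.frame")
  mods <- data.frame(animal_id = "a1", session_id = "s1", roi = rois)
  tc <- switching_timecourse(rt, mods)
  expect_equal(tc$first_coarse$mean, -d)
  expect_equal(tc$timecourse$mean[tc$timecourse$epoch == "Fine1"],
               rep(0, 3))
  # Fine2 equals Fine1 -> recovery at the first alpha trial
  expect_equal(tc$recovery_position, 1)
  expect_error(switching_timecourse(rt, mods[0, ]), "empty")
})

test_that("modulated ROIs show an immediate, significant drop on task switch", {
  rt <- std_responses()
  mod <- std_modulation()
  mset <- mod[mod$modulated, c("animal_id", "session_id", "roi")]
  expect_gte(nrow(mset), 40)
  tc <- switching_timecourse(rt, mset)
  # first coarse alpha trial: significantly negative change (immediate switch)
  expect_lt(tc$first_coarse$mean, 0)
  expect_lt(tc$first_coarse$p, 0.01)
  # unmodulated ROIs show no systematic time course
  un <- mod[!mod$modulated, c("animal_id", "session_id", "roi")]
  tc0 <- switching_timecourse(rt, un)
  expect_lt(abs(tc0$first_coarse$mean), 0.05)
})
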