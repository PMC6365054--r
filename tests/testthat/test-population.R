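# Pseudo-population construction, PCA trajectories, correlations,
# ROI removal, decoding, enrichment.

test_that("pseudo-population blocks have the right shape, averages and order", {
  el <- generate_session(noiseless_config(rois_per_animal = 4), seed = 5)
  coh <- structure(list(el), class = "ob_cohort")
  conds <- list(a.fine = list(odour = "alpha", epochs = c("Fine1", "Fine2")),
                a.coarse = list(odour = "alpha", epochs = "Coarse"))
  pop <- build_pseudopopulation(coh, conds, window = c(0, 10 / 30),
                                equalize = FALSE)
  expect_equal(dim(pop$mat), c(4, 20))  # 2 conditions x 10 timepoints
  expect_identical(pop$provenance$roi, 1:4)

  # averaging oracle: block equals the mean of single-trial transients
  d <- compute_dff(el$session)
  tr <- el$session$trials
  use <- which(tr$odour == "alpha" & tr$epoch == "Coarse" & !tr$probe)
  direct <- Reduce(`+`, lapply(use, function(t) {
    f0c <- floor(tr$odour_onset[t] * 30)
    d$dff[, f0c + (1:10)]
  })) / length(use)
  block <- pop$mat[, 11:20]
  expect_lt(max(abs(block - direct)), 1e-12)
})

test_that("PCA trajectories match an eigendecomposition oracle up to sign", {
  set.seed(4)
  mat <- matrix(rnorm(5 * 24), 5, 24)  # 5 ROIs x (2 cond x 12 time)
  pop <- structure(list(
    mat = mat,
    conditions = data.frame(label = c("c1", "c2"), first_col = c(1L, 13L),
                            n_time = 12L),
    provenance = data.frame(animal_id = "a", session_id = "s", roi = 1:5),
    time = (0:11) / 30, frame_rate = 30), class = "pseudo_population")
  traj <- pca_trajectories(pop)

  # oracle: eigendecomposition of the covariance of t(mat)
  X <- t(mat)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(Xc))
  for (j in 1:3) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_lt(max(abs(traj$loadings[, j] - v)), 1e-8)
  }
  expect_equal(traj$explained, ev$values / sum(ev$values), tolerance = 1e-10)
  # explained-variance fractions are in [0, 1] and non-increasing
  expect_true(all(traj$explained >= 0 & traj$explained <= 1))
  expect_true(all(diff(traj$explained) <= 1e-12))

  # scores: centered data projected on components -> zero mean per component
  sc <- as.matrix(traj$trajectories[, c("pc1", "pc2", "pc3")])
  expect_lt(max(abs(colMeans(sc))), 1e-10)
  expect_lt(max(abs(sc - Xc %*% traj$loadings)), 1e-8)

  # rank-1 data: PC1 explains everything
  u <- rnorm(5); w <- rnorm(24)
  pop1 <- pop; pop1$mat <- outer(u, w)
  traj1 <- pca_trajectories(pop1)
  expect_gt(traj1$explained[1], 1 - 1e-10)
})

test_that("fine-task trajectories separate from coarse but not across fine epochs", {
  coh <- std_cohort()
  traj <- pca_trajectories(suppressWarnings(build_pseudopopulation(coh)))
  d_task <- trajectory_separation(traj, "alpha.fine1", "alpha.coarse")
  d_rev <- trajectory_separation(traj, "alpha.fine1", "alpha.fine2")
  expect_gt(d_task, d_rev)

  # with modulation off the task separation falls to the noise floor set by
  # the within-task (Fine1 vs Fine2) distance; with modulation it exceeds it
  # many-fold
  cfg0 <- synth_config(modulation_delta = 0)
  coh0 <- generate_cohort(cfg0, seed = 43)
  traj0 <- suppressWarnings(pca_trajectories(build_pseudopopulation(coh0)))
  d_task0 <- trajectory_separation(traj0, "alpha.fine1", "alpha.coarse")
  d_rev0 <- trajectory_separation(traj0, "alpha.fine1", "alpha.fine2")
  expect_gt(d_task / d_rev, 4)
  expect_lt(d_task0 / d_rev0, 4)
})

test_that("Pearson correlation of response vectors matches the textbook formula", {
  # printed 4-ROI example vectors
  va <- c(0.41, 0.22, 0.63, 0.05)
  vp <- c(0.38, 0.25, 0.44, 0.11)
  rt <- make_response_table(
    roi = rep(1:4, 2), trial_id = rep(c(1L, 2L), each = 4),
    epoch = "Fine1", task = "fine",
    odour = rep(c("alpha", "alphaprime"), each = 4),
    rewarded = rep(c(TRUE, FALSE), each = 4),
    amplitude = c(va, vp))
  r <- response_correlation(rt)$r
  r_oracle <- sum((va - mean(va)) * (vp - mean(vp))) /
    sqrt(sum((va - mean(va))^2) * sum((vp - mean(vp))^2))
  expect_lt(abs(r - r_oracle), 1e-12)

  # identical vectors -> r = 1; negative scaling about the mean -> r = -1
  rt1 <- rt; rt1$amplitude <- c(va, va)
  expect_equal(response_correlation(rt1)$r, 1)
  rt2 <- rt; rt2$amplitude <- c(va, mean(va) - 2 * (va - mean(va)))
  expect_equal(response_correlation(rt2)$r, -1)

  # zero-variance vector -> NA with warning
  rt3 <- rt; rt3$amplitude <- c(va, rep(0.2, 4))
  expect_warning(r3 <- response_correlation(rt3)$r, "zero-variance")
  expect_true(is.na(r3))
})

test_that("removal correlation change matches brute-force recomputation", {
  # 6-ROI worked example with one strongly divergent ROI
  va <- c(0.40, 0.35, 0.20, 0.55, 0.30, 0.75)
  vp <- c(0.38, 0.33, 0.22, 0.50, 0.28, 0.35)
  rt <- make_response_table(
    roi = rep(1:6, 2), trial_id = rep(c(1L, 2L), each = 6),
    epoch = "Fine1", task = "fine",
    odour = rep(c("alpha", "alphaprime"), each = 6),
    rewarded = rep(c(TRUE, FALSE), each = 6),
    amplitude = c(va, vp))
  removal <- data.frame(animal_id = "a1", session_id = "s1", roi = 6L)
  cc <- removal_correlation_change(rt, removal, n_random = 50, seed = 2)
  r_full <- stats::cor(va, vp)
  r_rem <- stats::cor(va[-6], vp[-6])
  expect_lt(abs(cc$per_group$change - (r_rem - r_full) / r_full), 1e-12)
  expect_equal(cc$per_group$r_full, r_full)
  expect_gt(cc$per_group$change, 0)  # removing the divergent ROI decorrelates less

  # empty removal set -> change identically 0
  cc0 <- removal_correlation_change(rt, removal[0, ], n_random = 0)
  expect_equal(cc0$per_group$change, 0)
  expect_equal(cc0$mean_random_change, 0)

  # r_full invariant to ROI ordering
  perm <- c(3, 1, 6, 2, 5, 4)
  rt_perm <- rt
  rt_perm$roi <- rep(match(1:6, perm), 2)
  expect_equal(removal_correlation_change(rt_perm, removal[0, ],
                                          n_random = 0)$per_group$r_full,
               r_full)

  # removal covering the whole group errors
  expect_error(removal_correlation_change(
    rt, data.frame(animal_id = "a1", session_id = "s1", roi = 1:6)),
    "every ROI")

  # seeded random control is reproducible
  cc1 <- removal_correlation_change(rt, removal, n_random = 20, seed = 9)
  cc2 <- removal_correlation_change(rt, removal, n_random = 20, seed = 9)
  expect_identical(cc1$random, cc2$random)
})

test_that("the shrinkage LDA matches the closed-form discriminant and MASS::lda", {
  # fixed 2-D two-class data, lambda = 0 -> plain LDA
  set.seed(8)
  n <- 40
  X <- rbind(matrix(rnorm(2 * n, 0), ncol = 2),
             matrix(rnorm(2 * n, 1.6), ncol = 2))
  y <- rep(c("sminus", "splus"), each = n)
  fit <- bulbswitch:::.lda_fit(X, y, lambda = 0)
  # closed-form: delta_k(x) = x' S^-1 mu_k - 0.5 mu_k' S^-1 mu_k
  mu1 <- colMeans(X[1:n, ]); mu2 <- colMeans(X[n + 1:n, ])
  Xc <- rbind(sweep(X[1:n, ], 2, mu1), sweep(X[n + 1:n, ], 2, mu2))
  S <- crossprod(Xc) / (2 * n - 2)
  grid <- as.matrix(expand.grid(seq(-2, 3, 0.25), seq(-2, 3, 0.25)))
  colnames(grid) <- NULL
  d1 <- grid %*% solve(S, mu1) - 0.5 * c(mu1 %*% solve(S, mu1))
  d2 <- grid %*% solve(S, mu2) - 0.5 * c(mu2 %*% solve(S, mu2))
  oracle <- ifelse(d2 > d1, "splus", "sminus")
  pred <- bulbswitch:::.lda_predict(fit, grid)
  expect_identical(pred, as.vector(oracle))

  # cross-check against MASS::lda with equal priors on the same data
  skip_if_not_installed("MASS")
  m <- MASS::lda(X, grouping = factor(y), prior = c(0.5, 0.5))
  mp <- as.character(predict(m, grid)$class)
  expect_identical(pred, mp)
})

test_that("decoder behaviour: separable data, chance under label permutation", {
  # separable classes across 6 ROIs, margin >> spread
  set.seed(3)
  n_tr <- 18
  amp <- c(t(cbind(matrix(rnorm(9 * 6, 1, 0.05), 9),
                   matrix(rnorm(9 * 6, -1, 0.05), 9))))
  rt <- make_response_table(
    roi = rep(1:6, times = n_tr), trial_id = rep(1:n_tr, each = 6),
    epoch = rep(rep(c("Fine1", "Fine2"), each = 9 * 6), length.out = n_tr * 6),
    task = "fine",
    odour = rep(rep(c("alpha", "alphaprime"), 9), each = 6),
    rewarded = rep(rep(c(TRUE, FALSE), 9), each = 6),
    amplitude = amp)
  rep1 <- train_eval_decoder(rt, "fine", split_seed = 1, n_repeats = 10)
  expect_equal(rep1$accuracy, 100)

  # labels permuted -> chance on average over permutations (any single
  # permutation retains chance overlap with the true labels)
  set.seed(11)
  accs <- vapply(1:20, function(i) {
    rt_perm <- rt
    rt_perm$rewarded <- rep(sample(rep(c(TRUE, FALSE), 9)), each = 6)
    rt_perm$odour <- ifelse(rt_perm$rewarded, "alpha", "alphaprime")
    train_eval_decoder(rt_perm, "fine", split_seed = i,
                       n_repeats = 30)$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 50), 10)

  # class with < 3 trials errors
  expect_error(train_eval_decoder(rt[rt$trial_id %in% c(1:3, 2), ], "fine"),
               ">= 3")
})

test_that("KS enrichment statistic matches the ECDF-gap oracle", {
  x <- c(0.5, 1.2, 2.4, 3.3, 0.9)
  y <- c(0.4, 0.8, 1.1, 1.6, 2.0, 0.7)
  sel <- data.frame(animal_id = "a1", session_id = "s1",
                    roi = 1:11, index = c(x, y),
                    p = 0.01, t = 1, stringsAsFactors = FALSE)
  mod <- data.frame(animal_id = "a1", session_id = "s1", roi = 1:11,
                    modulated = rep(c(TRUE, FALSE), c(5, 6)),
                    stringsAsFactors = FALSE)
  enr <- selectivity_enrichment(sel, mod)
  # brute-force maximum ECDF gap
  grid <- sort(unique(c(x, y)))
  gap <- max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), 0)))
  expect_lt(abs(enr$ks_stat - gap), 1e-12)

  # identical distributions -> KS = 0 (up to ties)
  sel2 <- sel; sel2$index <- rep(c(1, 2, 3, 4, 5), length.out = 11)
  sel2$index[1:5] <- c(1, 2, 3, 4, 5)
  sel2$index[6:11] <- c(1, 2, 3, 4, 5, 1)
  enr2 <- selectivity_enrichment(sel2, mod)
  expect_lt(enr2$ks_stat, 0.2)
})

test_that("modulated ROIs are enriched for stimulus selectivity on synthetic cohorts", {
  rt <- std_responses()
  sel <- selectivity_tscore(rt)
  mod <- std_modulation()
  enr <- selectivity_enrichment(sel, mod)
  expect_lt(enr$ks_p, 0.05)
  # modulated group stochastically larger selectivity indices
  key <- paste(mod$animal_id, mod$session_id, mod$roi)
  is_mod <- mod$modulated[match(paste(sel$animal_id, sel$session_id, sel$roi),
                                key)]
  expect_gt(stats::median(sel$index[is_mod]), stats::median(sel$index[!is_mod]))
  # selective ROIs over-represented among the modulated
  expect_gt(enr$frac_selective_modulated, enr$frac_modulated)
})
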