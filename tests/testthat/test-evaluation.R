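test_that("Mann-Whitney AUC matches pair counting and handles ties", {
  expect_equal(auc_score(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(c(0.9, 0.8, 0.3, 0.2), c(0, 0, 1, 1)), 0)
  expect_equal(auc_score(c(0.7, 0.5, 0.5, 0.2), c(1, 0, 1, 0)),
               oracle_auc(c(0.7, 0.5, 0.5, 0.2), c(1, 0, 1, 0)))
  expect_equal(auc_score(rep(1, 6), rep(c(0, 1), 3)), 0.5)
  expect_error(auc_score(1:3, c(1, 1, 1)), "degenerate labels")

  set.seed(30)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    s <- sample(round(rnorm(n), 1)) # coarse values force ties
    l <- c(1, 0, rbinom(n - 2, 1, 0.5))
    expect_equal(auc_score(s, l), oracle_auc(s, l))
  }
})

test_that("AUC complement and monotone-transform identities hold", {
  set.seed(31)
  s <- rnorm(30)
  l <- rbinom(30, 1, 0.4)
  l[1:2] <- c(0, 1)
  expect_equal(auc_score(s, l) + auc_score(s, 1 - l), 1)
  expect_equal(auc_score(plogis(s), l), auc_score(s, l))
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  for (i in 1:10) {
    s <- rnorm(40)
    l <- c(0, 1, rbinom(38, 1, 0.5))
    ref <- as.numeric(suppressMessages(pROC::auc(l, s, direction = "<")))
    expect_equal(auc_score(s, l), ref)
  }
})

test_that("ROC curves are monotone, anchored, and integrate to the AUC", {
  cv <- roc_curve(c(5, 4, 1, 0), c(1, 1, 0, 0))
  expect_equal(cv$fpr[1], 0)
  expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1)
  expect_equal(cv$tpr[nrow(cv)], 1)
  expect_true(any(cv$fpr == 0 & cv$tpr == 1)) # perfect separation corner

  # binary scores give the degenerate 3-point sweep
  cv3 <- roc_curve(c(1, 1, 0, 0, 1), c(1, 0, 0, 0, 1))
  expect_equal(nrow(cv3), 3)

  set.seed(33)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    s <- round(rnorm(n), sample(0:2, 1))
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    cv <- roc_curve(s, l)
    expect_false(is.unsorted(cv$fpr))
    expect_false(is.unsorted(cv$tpr))
    expect_equal(attr(cv, "auc"), auc_score(s, l), tolerance = 1e-12)
  }
})

test_that("bootstrap bands are seeded, collapse at n_boot = 1, and cover", {
  set.seed(34)
  s <- c(rnorm(40, 2), rnorm(40, 0))
  l <- rep(c(1, 0), each = 40)

  set.seed(1)
  b1 <- bootstrap_bands(s, l, n_boot = 50)
  set.seed(1)
  b2 <- bootstrap_bands(s, l, n_boot = 50)
  expect_identical(b1, b2)

  set.seed(2)
  single <- bootstrap_bands(s, l, n_boot = 1)
  expect_equal(single$lower, single$upper)

  # envelope should cover the point-estimate curve almost everywhere
  for (sd_ in 3:5) {
    set.seed(sd_)
    b <- bootstrap_bands(s, l, n_boot = 200)
    point <- caldera:::tpr_at_fpr(roc_curve(s, l), b$fpr)
    covered <- mean(point >= b$lower - 1e-12 & point <= b$upper + 1e-12)
    expect_gte(covered, 0.9)
  }
})

test_that("grade thresholds maximise Youden's J and stay monotone", {
  # perfectly separated groups
  sep <- tibble::tibble(score = c(0, 0.1, 0.9, 1), grade = c(0, 0, 3, 3))
  th <- grade_thresholds(sep, boundaries = 3)
  expect_equal(th$sensitivity, 1)
  expect_equal(th$specificity, 1)
  expect_equal(th$youden_j, 1)

  # identical distributions: no usable threshold
  same <- tibble::tibble(score = rep(c(1, 2, 3), 2),
                         grade = rep(c(0, 3), each = 3))
  expect_equal(grade_thresholds(same, boundaries = 3)$youden_j, 0)

  set.seed(35)
  for (i in 1:20) {
    sc <- rnorm(60, mean = rep(c(0, 1, 2, 3, 4), each = 12) * 0.8)
    gr <- rep(0:4, each = 12)
    tab <- grade_thresholds(tibble::tibble(score = sc, grade = gr))
    expect_false(is.unsorted(tab$threshold))
    for (r in seq_len(nrow(tab))) {
      expect_equal(tab$youden_j[r], oracle_best_j(sc, gr >= tab$boundary[r]))
    }
  }

  expect_error(grade_thresholds(sep, boundaries = c(3, 4)), "missing grade")
})

test_that("stratified AUC scores each activity and flags missing classes", {
  d <- tibble::tibble(score = c(1, 2, 3, 4, 2, 5),
                      label = c(0, 1, 0, 1, 0, 1),
                      activity = "sitting")
  one <- stratified_auc(d)
  expect_equal(nrow(one), 1)
  expect_equal(one$auc, auc_score(d$score, d$label))

  d$activity <- c(rep("sitting", 4), "walking", "other")
  d$label <- c(0, 1, 0, 1, 0, 0)
  st <- stratified_auc(d)
  expect_equal(st$flag[st$activity == "walking"], "missing class")
  expect_true(is.na(st$auc[st$activity == "walking"]))
  expect_equal(st$flag[st$activity == "sitting"], "")
})

test_that("top-window patterns recompute from the sorted window list", {
  set.seed(36)
  W <- matrix(rnorm(500 * 32), ncol = 32)
  g <- genome_abs_diff(0L, 31L)
  out <- cgp_evaluate_matrix(g, W)

  p1 <- top_window_pattern(g, W, k_list = 1)
  expect_equal(p1$mean_value, W[which.max(out), ])

  p <- top_window_pattern(g, W, k_list = c(10, 100))
  ord <- order(out, decreasing = TRUE)
  expect_equal(p$mean_value[p$k == 10], colMeans(W[ord[1:10], ]))
  expect_equal(p$mean_value[p$k == 100], colMeans(W[ord[1:100], ]))

  expect_error(top_window_pattern(g, W, k_list = 1000),
               "insufficient windows")
})

test_that("episode summaries band epochs and merge only adjacent episodes", {
  # recording: rest | grade-4 dyskinesia | rest | grade-4 | rest, 20 s each
  cfg <- synthetic_config(segment_duration_s = 20, seed = 2)
  set.seed(2)
  pieces <- list(generate_segment("rest", config = cfg),
                 generate_segment("dyskinesia", 4, cfg, carrier = "rest"),
                 generate_segment("rest", config = cfg),
                 generate_segment("dyskinesia", 4, cfg, carrier = "rest"),
                 generate_segment("rest", config = cfg))
  acc <- do.call(rbind, lapply(pieces, `[[`, "accel"))
  rec <- new_recording("ep", tibble::tibble(
    t = (seq_len(nrow(acc)) - 1) / 100,
    ax = acc[, 1], ay = acc[, 2], az = acc[, 3]), 100, "left_arm")

  g <- genome_abs_diff(5L, 18L) # peak-minus-dip style contrast
  model <- classifier_model(g, "time")
  expect_error(episode_summary(rec, model, 20), "not calibrated")

  # calibrate on scores of independent rest / grade-4 segments
  set.seed(3)
  cal_scores <- c(
    vapply(1:8, function(i) {
      segment_score(g, magnitude_of(generate_segment("rest", config = cfg)))
    }, numeric(1)),
    vapply(1:8, function(i) {
      segment_score(g, magnitude_of(
        generate_segment("dyskinesia", 4, cfg, carrier = "rest")))
    }, numeric(1)))
  model <- fit_thresholds(model,
                          tibble::tibble(score = cal_scores,
                                         grade = rep(c(0, 4), each = 8)),
                          boundaries = c(3, 4))

  tl <- episode_summary(rec, model, epoch_s = 20)
  expect_equal(nrow(tl$epochs), 5)
  # two planted blocks separated by a lower epoch: two episodes, no bridging
  expect_equal(nrow(tl$episodes), 2)
  expect_equal(tl$episodes$start_s, c(20, 60))
  expect_equal(tl$episodes$end_s, c(40, 80))
  expect_true(all(tl$episodes$band >= 3))
  # accounted duration equals the sum of merged epochs exactly
  expect_equal(sum(tl$episodes$end_s - tl$episodes$start_s),
               sum(tl$episodes$n_epochs) * 20)

  # a fully quiet recording yields no episodes
  quiet <- new_recording("q", rec$data[1:2000, ], 100, "left_arm")
  expect_equal(nrow(episode_summary(quiet, model, 20)$episodes), 0)

  # sleep epochs are excluded from banding
  tl_sleep <- episode_summary(rec, model, epoch_s = 20,
                              sleep_intervals = tibble::tibble(start_s = 60,
                                                               end_s = 80))
  expect_equal(nrow(tl_sleep$episodes), 1)
  expect_true(is.na(tl_sleep$epochs$band[4]))
})

test_that("waveform similarity is symmetric-ish and shift tolerant", {
  tmpl <- caldera_template(32)
  expect_equal(waveform_similarity(tmpl, tmpl), 1)
  shifted <- c(rep(0, 5), tmpl[1:27])
  expect_gt(waveform_similarity(shifted, tmpl), 0.95)
  expect_gt(waveform_similarity(tmpl, shifted), 0.95)
})

test_that("plot builders return ggplot objects without evaluation errors", {
  set.seed(40)
  s <- c(rnorm(20, 1.5), rnorm(20))
  l <- rep(c(1, 0), each = 20)
  cv <- roc_curve(s, l)
  set.seed(1)
  b <- bootstrap_bands(s, l, n_boot = 20)
  expect_s3_class(autoplot(cv, bands = b), "ggplot")

  W <- matrix(rnorm(100 * 32), ncol = 32)
  p <- top_window_pattern(genome_abs_diff(), W, k_list = c(5, 20))
  expect_s3_class(autoplot(p), "ggplot")
})
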