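test_that("caldera template has two ordered lobes with an interior dip", {
  tmpl <- caldera_template(64)
  expect_true(all(tmpl >= 0))
  expect_equal(max(tmpl), 1)

  # lobe extents: first lobe strictly wider than the second
  active <- tmpl > 1e-3
  runs <- rle(active)
  lobe_lens <- runs$lengths[runs$values]
  expect_equal(length(lobe_lens), 2)
  expect_gt(lobe_lens[1], lobe_lens[2])

  # the dip is a local minimum strictly inside the first lobe
  lobe1 <- which(active)[seq_len(lobe_lens[1])]
  interior <- tmpl[lobe1]
  mins <- which(diff(sign(diff(interior))) > 0) + 1
  expect_true(length(mins) >= 1)
  expect_true(all(mins > 1 & mins < length(interior)))

  # dip_depth 0 removes the interior minimum
  flat <- caldera_template(64, dip_depth = 0)
  lobe1_flat <- flat[lobe1]
  expect_length(which(diff(sign(diff(lobe1_flat))) > 0), 0)

  expect_error(caldera_template(16), "invalid template")
  expect_error(caldera_template(64, lobe1_frac = 0.2, lobe2_frac = 0.3),
               "invalid template")
})

test_that("caldera template is shape-preserving under resampling", {
  t32 <- caldera_template(32)
  t64 <- caldera_template(64)
  interpolated <- approx(seq(0, 1, length.out = 32), t32,
                         xout = seq(0, 1, length.out = 64))$y
  expect_gt(cor(t64, interpolated), 0.99)
})

test_that("segment classes have the designed ordering properties", {
  cfg <- synthetic_config()
  set.seed(50)
  rest <- generate_segment("rest", config = cfg)
  walk <- generate_segment("walking", config = cfg)
  expect_lt(sd(magnitude_of(rest)), sd(magnitude_of(walk)))
  expect_equal(rest$activity, "sitting")
  expect_equal(walk$activity, "walking")
  expect_equal(generate_segment("voluntary", config = cfg)$activity, "other")

  # occurrence rate is monotone in grade (same seed stream per draw)
  n3 <- n4 <- numeric(20)
  for (i in 1:20) {
    set.seed(100 + i)
    n3[i] <- nrow(generate_segment("dyskinesia", 3, cfg)$occurrences)
    set.seed(100 + i)
    n4[i] <- nrow(generate_segment("dyskinesia", 4, cfg)$occurrences)
  }
  expect_gt(mean(n4), mean(n3))

  expect_error(generate_segment("jogging"), "unknown class")
})

test_that("planted occurrences are recoverable by matched filtering", {
  study <- generate_study(synthetic_config())
  tmpl <- caldera_template(32)
  detected <- 0
  total <- 0
  for (rid in unique(study$truth$recording_id)) {
    x <- magnitude(study$recordings[[rid]])$magnitude
    w <- extract_windows(x)
    cc <- suppressWarnings(apply(w, 1, cor, y = tmpl))
    cc[is.na(cc)] <- 0
    tt <- study$truth[study$truth$recording_id == rid, ]
    for (r in seq_len(nrow(tt))) {
      i0 <- max(1, round(tt$start_s[r] * 100) - 15)
      i1 <- min(length(cc), round(tt$start_s[r] * 100) + 15)
      total <- total + 1
      detected <- detected + (max(cc[i0:i1]) > 0.5)
    }
  }
  expect_gte(detected / total, 0.9)
})

test_that("studies are deterministic with configured counts and splits", {
  cfg <- synthetic_config(counts = small_counts(), seed = 77)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$segments, s2$segments)
  expect_identical(lapply(s1$recordings, `[[`, "data"),
                   lapply(s2$recordings, `[[`, "data"))
  expect_identical(s1$truth, s2$truth)

  # class counts per split match the configuration exactly
  got <- dplyr::count(s1$segments, split, class)
  want <- dplyr::summarise(dplyr::group_by(small_counts(), split, class),
                           n = sum(n), .groups = "drop")
  expect_equal(dplyr::arrange(got, split, class),
               dplyr::arrange(want, split, class))

  # splits are disjoint by recording
  expect_equal(anyDuplicated(s1$segments$recording_id), 0)
})

test_that("grade-0 and grade-3/4 segments separate under a matched filter", {
  study <- generate_study(synthetic_config())
  segs <- dplyr::bind_rows(study_segments(study, "train"),
                           study_segments(study, "test"),
                           study_segments(study, "holdout"))
  segs <- segs[segs$grade == 0 | segs$grade >= 3, ]
  scores <- vapply(segs$series, oracle_matched_filter, numeric(1))
  expect_gte(auc_score(scores, segs$grade >= 3), 0.95)
})

test_that("holdout is the harder split for a fixed model, on average", {
  diffs <- numeric(0)
  for (s in c(42, 7, 99, 123, 2024)) {
    study <- generate_study(synthetic_config(seed = s))
    aucs <- vapply(c("test", "holdout"), function(sp) {
      segs <- study_segments(study, sp)
      segs <- segs[segs$grade == 0 | segs$grade >= 3, ]
      auc_score(vapply(segs$series, oracle_matched_filter, numeric(1)),
                segs$grade >= 3)
    }, numeric(1))
    diffs <- c(diffs, aucs["test"] - aucs["holdout"])
  }
  expect_gte(mean(diffs), 0)
})

test_that("walking and dyskinesia overlap spectrally but not in shape", {
  study <- generate_study(synthetic_config())
  segs <- study_segments(study, "train")
  argmax_bin <- function(x) which.max(long_term_spectrum(x)$density)
  walk_bins <- vapply(segs$series[segs$activity == "walking" &
                                    segs$grade == 0],
                      argmax_bin, integer(1))
  dysk_bins <- vapply(segs$series[segs$grade >= 3], argmax_bin, integer(1))
  expect_true(length(intersect(walk_bins, dysk_bins)) >= 1)
  # both concentrate in the low-frequency band
  expect_true(all(c(walk_bins, dysk_bins) <= 5))

  # time-domain shapes differ: matched-filter peak higher for dyskinesia
  mf_walk <- vapply(segs$series[segs$activity == "walking" &
                                  segs$grade == 0],
                    oracle_matched_filter, numeric(1))
  mf_dysk <- vapply(segs$series[segs$grade >= 3], oracle_matched_filter,
                    numeric(1))
  expect_gt(median(mf_dysk), median(mf_walk))
})

test_that("every generated segment yields at least one window", {
  study <- small_study()
  lens <- vapply(study_segments(study, "train")$series, length, integer(1))
  expect_true(all(lens >= 32))
})

test_that("gyroscope channels carry the pattern at reduced amplitude", {
  cfg <- synthetic_config()
  ratios <- numeric(10)
  for (i in 1:10) {
    set.seed(200 + i)
    seg <- generate_segment("dyskinesia", 4, cfg, carrier = "rest")
    acc_peak <- oracle_matched_filter(magnitude_of(seg))
    gyr_peak <- oracle_matched_filter(sqrt(rowSums(seg$gyro^2)))
    ratios[i] <- gyr_peak / acc_peak
  }
  expect_lt(median(ratios), 0.75)
})
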