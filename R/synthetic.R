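#' Caldera burst template
#'
#' The planted dyskinetic acceleration pattern: two rise-and-fall lobes, the
#' second strictly shorter than the first, with a dip notched into the top of
#' the first lobe (the "caldera"). Defined as a smooth function of relative
#' position and sampled at `length_samples` points, so resampling to another
#' length preserves the shape. Values are non-negative with unit peak; grade
#' amplitude scaling is applied by the segment generator.
#'
#' @param length_samples Number of samples (>= 32 covers one window at
#'   100 Hz; default 32, i.e. 0.32 s).
#' @param lobe1_frac,lobe2_frac Fractions of the template occupied by the
#'   first and second lobe; the first must exceed the second.
#' @param gap_frac Fraction separating the lobes.
#' @param dip_depth Relative depth of the caldera dip in (0, 1); 0 removes
#'   the dip.
#' @param dip_width Relative width of the dip within lobe 1.
#' @param lobe2_amp Peak of the second lobe relative to the first.
#' @return Numeric vector of `length_samples` non-negative values, max 1.
#' @export
caldera_template <- function(length_samples = 32L, lobe1_frac = 0.55,
                             lobe2_frac = 0.30, gap_frac = 0.05,
                             dip_depth = 0.35, dip_width = 0.12,
                             lobe2_amp = 0.85) {
  if (length_samples < 32 || lobe1_frac <= lobe2_frac || lobe1_frac <= 0 ||
      lobe2_frac <= 0 || lobe1_frac + gap_frac + lobe2_frac > 1 ||
      dip_depth < 0 || dip_depth >= 1 || lobe2_amp <= 0 || lobe2_amp > 1) {
    stop("invalid template: need length >= 32, 0 < lobe2_frac < lobe1_frac, ",
         "fractions summing to <= 1, dip_depth in [0, 1), lobe2_amp in (0, 1]",
         call. = FALSE)
  }
  u <- (seq_len(length_samples) - 0.5) / length_samples
  v <- numeric(length_samples)
  in1 <- u < lobe1_frac
  s1 <- u[in1] / lobe1_frac
  v[in1] <- sin(pi * s1)^0.7 *
    (1 - dip_depth * exp(-((s1 - 0.5) / dip_width)^2))
  lo2 <- lobe1_frac + gap_frac
  in2 <- u >= lo2 & u < lo2 + lobe2_frac
  s2 <- (u[in2] - lo2) / lobe2_frac
  v[in2] <- lobe2_amp * sin(pi * s2)^2
  v / max(v)
}

#' Synthetic study configuration
#'
#' Defaults define the study conditions every pipeline test runs under:
#' 100 Hz tri-axial recordings of 10 s segments; grade-0 segments at rest,
#' walking (1.8 Hz cadence with harmonics, spectrally overlapping dyskinesia)
#' or performing voluntary movements; dyskinetic segments carrying caldera
#' bursts whose rate and amplitude rise with clinical grade
#' (grade -> occurrences/min, peak amplitude in g:
#' 1 -> 4, 0.3; 2 -> 8, 0.6; 3 -> 14, 1.0; 4 -> 22, 1.5). Train/test/holdout
#' splits are disjoint by recording and the holdout split uses a higher
#' sensor noise level, standing in for a different set of sensor modules.
#' Gyroscope channels carry the planted pattern at half amplitude.
#'
#' @param sample_rate Samples per second (100).
#' @param segment_duration_s Duration of each generated segment.
#' @param counts Tibble with columns `split`, `class`
#'   (rest/walking/voluntary/dyskinesia), `grade`, `n`.
#' @param grade_rates Named numeric: caldera occurrences per minute per grade.
#' @param grade_amps Named numeric: caldera peak amplitude (g) per grade.
#' @param walking_cadence_hz Walking fundamental frequency.
#' @param walking_amp Walking fundamental amplitude (g): a length-2 range
#'   sampled per segment (energy overlapping the dyskinetic bursts), or a
#'   single fixed value.
#' @param noise_sd Named numeric: accelerometer noise sd (g) per split.
#' @param fractional_grade_prob Probability a dyskinetic segment's label is
#'   shifted +-0.5 to emulate rater disagreement averaging.
#' @param seed Master seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(sample_rate = 100,
                             segment_duration_s = 10,
                             counts = default_counts(),
                             grade_rates = c(`1` = 4, `2` = 8, `3` = 14,
                                             `4` = 22),
                             grade_amps = c(`1` = 0.3, `2` = 0.6, `3` = 1.0,
                                            `4` = 1.5),
                             walking_cadence_hz = 1.8,
                             walking_amp = c(0.35, 0.75),
                             noise_sd = c(train = 0.05, test = 0.05,
                                          holdout = 0.08),
                             fractional_grade_prob = 0.2,
                             seed = 42L) {
  stopifnot(segment_duration_s > 0.32,
            !is.unsorted(grade_amps), !is.unsorted(grade_rates))
  structure(list(sample_rate = sample_rate,
                 segment_duration_s = segment_duration_s,
                 counts = counts, grade_rates = grade_rates,
                 grade_amps = grade_amps,
                 walking_cadence_hz = walking_cadence_hz,
                 walking_amp = walking_amp, noise_sd = noise_sd,
                 fractional_grade_prob = fractional_grade_prob,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_counts <- function() {
  grid <- function(split, rest, walking, voluntary, g1, g2, g3, g4) {
    tibble::tibble(
      split = split,
      class = c("rest", "walking", "voluntary", rep("dyskinesia", 4)),
      grade = c(0, 0, 0, 1, 2, 3, 4),
      n = c(rest, walking, voluntary, g1, g2, g3, g4))
  }
  dplyr::bind_rows(grid("train", 12, 10, 8, 4, 4, 10, 10),
                   grid("test", 8, 6, 6, 3, 3, 8, 8),
                   grid("holdout", 8, 6, 6, 3, 3, 8, 8))
}

sensor_sites <- function() {
  c("left_arm", "right_arm", "left_leg", "right_leg", "trunk", "head")
}

# Smooth slowly drifting unit gravity direction (orientation drift of a worn
# sensor); returns an n x 3 matrix of unit vectors.
gravity_direction <- function(n, sample_rate) {
  t <- (seq_len(n) - 1) / sample_rate
  th <- 0.08 * sin(2 * pi * 0.02 * t + stats::runif(1, 0, 2 * pi))
  ph <- 0.08 * sin(2 * pi * 0.013 * t + stats::runif(1, 0, 2 * pi))
  cbind(sin(th) * cos(ph), sin(ph), cos(th) * cos(ph))
}

# Per-segment stride amplitude is drawn from a range so that the energy of
# walking segments overlaps the energy added by dyskinetic bursts: segment
# energy alone cannot separate the classes, only temporal shape (or lack of
# it) can. This is what makes the walking confounder meaningful for the
# time-vs-spectral comparison.
walking_component <- function(t, cadence, amp_range) {
  amp <- if (length(amp_range) == 2) {
    stats::runif(1, amp_range[1], amp_range[2])
  } else {
    amp_range
  }
  smooth <- amp * (sin(2 * pi * cadence * t + stats::runif(1, 0, 2 * pi)) +
                     stats::runif(1, 0.4, 0.6) *
                       sin(2 * pi * 2 * cadence * t +
                             stats::runif(1, 0, 2 * pi)) +
                     stats::runif(1, 0.15, 0.25) *
                       sin(2 * pi * 3 * cadence * t +
                             stats::runif(1, 0, 2 * pi)))
  # Heel-strike transients: one short impact per step, with broadband
  # content reaching ~10 Hz. They give walking the same high-frequency
  # spectral footprint as the short second lobe of the dyskinetic burst
  # (band overlap), while looking nothing like it in the time domain.
  strikes <- numeric(length(t))
  step_times <- seq(stats::runif(1, 0, 1 / cadence), max(t), by = 1 / cadence)
  for (tk in step_times) {
    tk <- tk + stats::rnorm(1, sd = 0.01)
    a <- 1.5 * amp * stats::runif(1, 0.8, 1.2)
    strikes <- strikes + a * exp(-((t - tk) / 0.02)^2) *
      cos(2 * pi * 9 * (t - tk))
  }
  smooth + strikes
}

voluntary_component <- function(t, n_bursts) {
  out <- numeric(length(t))
  for (i in seq_len(n_bursts)) {
    centre <- stats::runif(1, min(t), max(t))
    width <- stats::runif(1, 0.3, 0.6)
    freq <- stats::runif(1, 0.8, 2.2)
    amp <- stats::runif(1, 0.5, 0.9)
    out <- out + amp * exp(-((t - centre) / width)^2) *
      sin(2 * pi * freq * (t - centre))
  }
  out
}

# Plant caldera bursts; returns the additive axial component and the planted
# occurrence intervals (seconds).
plant_calderas <- function(n, sample_rate, rate_per_min, amplitude,
                           duration_s) {
  burst <- numeric(n)
  n_occ <- max(1L, stats::rpois(1, rate_per_min * duration_s / 60))
  occ <- tibble::tibble(start_s = numeric(0), end_s = numeric(0))
  for (i in seq_len(n_occ)) {
    warp <- stats::runif(1, 0.9, 1.1)
    len <- max(32L, as.integer(round(32 * warp)))
    if (len >= n) next
    start <- sample.int(n - len, 1L)
    tmpl <- caldera_template(len)
    amp <- amplitude * stats::runif(1, 0.9, 1.1)
    burst[start:(start + len - 1L)] <-
      burst[start:(start + len - 1L)] + amp * tmpl
    occ <- dplyr::bind_rows(occ, tibble::tibble(
      start_s = (start - 1) / sample_rate,
      end_s = (start - 1 + len) / sample_rate))
  }
  list(burst = burst, occurrences = occ)
}

#' Generate one labelled synthetic segment
#'
#' Draws a tri-axial accelerometer + gyroscope segment of the requested
#' class. Rest is gravity plus sensor noise; walking adds a cadence
#' fundamental with harmonics along the gravity axis; voluntary movement adds
#' smooth bell-shaped bursts; dyskinesia superposes amplitude- and
#' rate-graded caldera bursts (timing jittered, +-10% time-warped) along the
#' instantaneous gravity axis on a rest or walking carrier. Gyroscope
#' channels carry the same structure at half amplitude.
#'
#' @param class_spec `"rest"`, `"walking"`, `"voluntary"` or `"dyskinesia"`.
#' @param grade Clinical grade 1-4 (dyskinesia only).
#' @param config A [synthetic_config()].
#' @param noise_sd Accelerometer noise sd (g) for this segment.
#' @param carrier For dyskinesia, `"rest"` or `"walking"`; default random.
#' @return A list: `accel` (n x 3), `gyro` (n x 3), `activity` tag
#'   (`sitting`/`walking`/`other`), `grade`, `occurrences` (tibble of planted
#'   burst intervals, seconds).
#' @export
generate_segment <- function(class_spec, grade = 0,
                             config = synthetic_config(),
                             noise_sd = 0.05, carrier = NULL) {
  if (!class_spec %in% c("rest", "walking", "voluntary", "dyskinesia")) {
    stop("unknown class: ", class_spec, call. = FALSE)
  }
  sr <- config$sample_rate
  n <- as.integer(round(config$segment_duration_s * sr))
  t <- (seq_len(n) - 1) / sr
  gdir <- gravity_direction(n, sr)

  carrier_axial <- numeric(n)  # confounder movement along the gravity axis
  burst_axial <- numeric(n)    # planted dyskinetic bursts
  activity <- "sitting"
  occurrences <- tibble::tibble(start_s = numeric(0), end_s = numeric(0))

  # Postural sway: slow axial oscillation present in every segment. Together
  # with the per-recording calibration bias (added below) it gives grade-0
  # segments realistic mean/energy diversity, so gross signal level cannot
  # separate the classes -- the planted burst shape has to.
  carrier_axial <- carrier_axial + stats::runif(1, 0, 0.15) *
    sin(2 * pi * stats::runif(1, 0.1, 0.4) * t + stats::runif(1, 0, 2 * pi))

  base_class <- class_spec
  if (class_spec == "dyskinesia") {
    stopifnot(grade >= 1, grade <= 4)
    if (is.null(carrier)) {
      carrier <- if (stats::runif(1) < 0.5) "rest" else "walking"
    }
    base_class <- carrier
  }
  if (base_class == "walking") {
    carrier_axial <- carrier_axial +
      walking_component(t, config$walking_cadence_hz, config$walking_amp)
    activity <- "walking"
  } else if (base_class == "voluntary") {
    carrier_axial <- carrier_axial +
      voluntary_component(t, n_bursts = sample(2:4, 1))
    activity <- "other"
  }
  if (class_spec == "dyskinesia") {
    planted <- plant_calderas(n, sr, config$grade_rates[[as.character(grade)]],
                              config$grade_amps[[as.character(grade)]],
                              config$segment_duration_s)
    burst_axial <- planted$burst
    occurrences <- planted$occurrences
  }

  # Per-recording accelerometer calibration bias: raw uncalibrated sensors
  # differ by a few hundredths of a g per axis, and each segment here is its
  # own recording.
  bias <- stats::rnorm(3, sd = 0.05)
  accel <- gdir * (1 + carrier_axial + burst_axial) +
    matrix(bias, n, 3, byrow = TRUE) +
    matrix(stats::rnorm(3 * n, sd = noise_sd), ncol = 3)
  # Gyroscope: sway/walking/voluntary rotate the limb at full scale, but the
  # planted pattern appears at half amplitude (half SNR), with its own
  # per-recording bias -- rotational recordings are the harder data source.
  gyro_bias <- stats::rnorm(3, sd = 0.05)
  gyro <- gdir * (carrier_axial + 0.5 * burst_axial) +
    matrix(gyro_bias, n, 3, byrow = TRUE) +
    matrix(stats::rnorm(3 * n, sd = noise_sd), ncol = 3)

  list(accel = accel, gyro = gyro, activity = activity,
       grade = if (class_spec == "dyskinesia") grade else 0,
       occurrences = occurrences)
}

#' Generate a full synthetic study
#'
#' Seeded end-to-end data source: one recording per segment, class counts per
#' split as configured, disjoint splits, holdout generated with its own noise
#' level, ground-truth burst intervals retained, and rater-averaged
#' fractional grades emitted for a configurable fraction of dyskinetic
#' segments.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_study`: list with `recordings` (named list of
#'   `recording` objects), `segments` (tibble: `segment_id`, `recording_id`,
#'   `split`, `class`, `grade`, `activity`, `site`), `labels` (labels table,
#'   see [read_labels()]), `truth` (planted burst intervals), `config`.
#' @export
generate_study <- function(config = synthetic_config()) {
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  rows <- config$counts[rep(seq_len(nrow(config$counts)),
                            config$counts$n), ]
  recordings <- list()
  segs <- vector("list", nrow(rows))
  labels <- vector("list", nrow(rows))
  truth <- vector("list", nrow(rows))
  sites <- sensor_sites()

  for (i in seq_len(nrow(rows))) {
    split <- rows$split[i]
    cls <- rows$class[i]
    grade <- rows$grade[i]
    seg <- generate_segment(cls, grade, config,
                            noise_sd = config$noise_sd[[split]])
    label_grade <- seg$grade
    if (cls == "dyskinesia" &&
        stats::runif(1) < config$fractional_grade_prob) {
      shift <- if (grade == 4) -0.5 else sample(c(-0.5, 0.5), 1)
      label_grade <- label_grade + shift
    }
    rid <- sprintf("%s_%03d", split, i)
    site <- sites[(i - 1L) %% length(sites) + 1L]
    n <- nrow(seg$accel)
    data <- tibble::tibble(t = (seq_len(n) - 1) / config$sample_rate,
                           ax = seg$accel[, 1], ay = seg$accel[, 2],
                           az = seg$accel[, 3],
                           gx = seg$gyro[, 1], gy = seg$gyro[, 2],
                           gz = seg$gyro[, 3])
    recordings[[rid]] <- new_recording(rid, data, config$sample_rate, site)
    segs[[i]] <- tibble::tibble(segment_id = rid, recording_id = rid,
                                split = split, class = cls,
                                grade = label_grade, activity = seg$activity,
                                site = site)
    labels[[i]] <- tibble::tibble(recording_id = rid, start_s = 0,
                                  end_s = config$segment_duration_s,
                                  grade = label_grade,
                                  activity = seg$activity, site = site)
    if (nrow(seg$occurrences)) {
      truth[[i]] <- dplyr::mutate(seg$occurrences, recording_id = rid,
                                  planted_grade = grade, .before = 1)
    }
  }

  structure(list(recordings = recordings,
                 segments = dplyr::bind_rows(segs),
                 labels = dplyr::bind_rows(labels),
                 truth = dplyr::bind_rows(truth),
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", nrow(x$segments), " segments (",
      paste(sprintf("%s: %d", names(table(x$segments$split)),
                    as.integer(table(x$segments$split))), collapse = ", "),
      "), seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Segment table of a study split, ready for training
#'
#' Extracts the magnitude series of every segment in a split as the tibble
#' accepted by [fitness()], [evolve()] and [multi_run_select()].
#'
#' @param study A `synthetic_study`.
#' @param split `"train"`, `"test"` or `"holdout"`.
#' @param channels `"accel"` or `"gyro"`.
#' @return Tibble with `segment_id`, `grade`, `activity`, `split` and a
#'   `series` list column of magnitude series.
#' @export
study_segments <- function(study, split = c("train", "test", "holdout"),
                           channels = c("accel", "gyro")) {
  split <- match.arg(split)
  channels <- match.arg(channels)
  seg <- study$segments[study$segments$split == split, ]
  seg$series <- lapply(seg$recording_id, function(rid) {
    magnitude(study$recordings[[rid]], channels)$magnitude
  })
  seg[c("segment_id", "grade", "activity", "split", "series")]
}
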