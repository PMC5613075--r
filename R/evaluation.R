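#' Area under the ROC curve (Mann-Whitney)
#'
#' AUC computed by rank statistics: the probability that a randomly drawn
#' positive scores above a randomly drawn negative, with ties counting one
#' half. Equivalent to exhaustive pair counting
#' (#\{pos > neg\} + 0.5 #\{ties\}) / (n_pos * n_neg).
#'
#' @param scores Numeric vector of classifier scores.
#' @param labels Logical (or 0/1) vector; `TRUE` marks the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("degenerate labels: both classes must be non-empty", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve
#'
#' Sweeps every distinct score as a threshold and returns the ROC operating
#' points. The trapezoidal area under the returned curve equals [auc_score()]
#' up to floating-point rounding.
#'
#' @inheritParams auc_score
#' @return A `roc_curve` tibble with columns `threshold`, `fpr`, `tpr`,
#'   starting at (0, 0) and ending at (1, 1); attribute `auc` holds the area.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("degenerate labels: both classes must be non-empty", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(!l)[last_of_tie]
  out <- tibble::tibble(threshold = c(Inf, s[last_of_tie]),
                        fpr = c(0, fp / n_neg),
                        tpr = c(0, tp / n_pos))
  auc <- sum(diff(out$fpr) * (out$tpr[-1] + out$tpr[-nrow(out)]) / 2)
  structure(out, auc = auc, class = c("roc_curve", class(out)))
}

#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, bands = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr))
  if (!is.null(bands)) {
    p <- p + ggplot2::geom_ribbon(
      data = bands,
      ggplot2::aes(x = .data$fpr, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.3)
  }
  p + ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

# Step interpolation of a ROC curve: highest TPR attained at FPR <= grid.
tpr_at_fpr <- function(curve, fpr_grid) {
  vapply(fpr_grid, function(f) max(curve$tpr[curve$fpr <= f + 1e-12]),
         numeric(1))
}

#' Bootstrap confidence bands for a ROC curve
#'
#' Stratified bootstrap: positives and negatives are resampled with
#' replacement within class, the ROC recomputed for each resample, and the
#' 2.5/97.5 percentile envelope of the TPR taken on a fixed FPR grid.
#'
#' @inheritParams auc_score
#' @param n_boot Number of bootstrap resamples.
#' @param fpr_grid FPR grid on which the envelope is evaluated.
#' @return A `roc_bands` tibble with columns `fpr`, `lower`, `upper`, and an
#'   `auc_quantiles` attribute with the bootstrap AUC interval.
#' @export
bootstrap_bands <- function(scores, labels, n_boot = 200,
                            fpr_grid = seq(0, 1, by = 0.01)) {
  labels <- as.logical(labels)
  stopifnot(n_boot >= 1)
  pos <- which(labels)
  neg <- which(!labels)
  if (!length(pos) || !length(neg)) {
    stop("degenerate labels: both classes must be non-empty", call. = FALSE)
  }
  tprs <- matrix(NA_real_, n_boot, length(fpr_grid))
  aucs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- c(pos[sample.int(length(pos), replace = TRUE)],
             neg[sample.int(length(neg), replace = TRUE)])
    cv <- roc_curve(scores[idx], labels[idx])
    tprs[b, ] <- tpr_at_fpr(cv, fpr_grid)
    aucs[b] <- attr(cv, "auc")
  }
  out <- tibble::tibble(
    fpr = fpr_grid,
    lower = apply(tprs, 2, stats::quantile, probs = 0.025, names = FALSE),
    upper = apply(tprs, 2, stats::quantile, probs = 0.975, names = FALSE))
  structure(out,
            auc_quantiles = stats::quantile(aucs, c(0.025, 0.5, 0.975)),
            class = c("roc_bands", class(out)))
}

#' Per-grade optimal thresholds with sensitivity and specificity
#'
#' For each adjacent grade boundary (>=1, >=2, >=3, =4) the score threshold
#' maximising Youden's J (sensitivity + specificity - 1) is found by an
#' exhaustive sweep over cut-points between distinct scores; the resulting
#' thresholds are coerced monotone non-decreasing across boundaries.
#'
#' @param scores_by_grade Data frame with numeric columns `score` and `grade`
#'   (0-4, possibly fractional).
#' @param boundaries Grade boundaries to threshold (default 1, 2, 3, 4).
#' @return A tibble with columns `boundary`, `threshold`, `sensitivity`,
#'   `specificity`, `youden_j`.
#' @export
grade_thresholds <- function(scores_by_grade, boundaries = 1:4) {
  stopifnot(all(c("score", "grade") %in% names(scores_by_grade)))
  res <- purrr::map_dfr(boundaries, function(b) {
    pos <- scores_by_grade$grade >= b
    if (!any(pos) || all(pos)) {
      stop("missing grade: no segments ", if (!any(pos)) "at or above " else
           "below ", "boundary ", b, call. = FALSE)
    }
    best <- best_youden(scores_by_grade$score, pos)
    tibble::tibble(boundary = b, threshold = best$threshold,
                   sensitivity = best$sensitivity,
                   specificity = best$specificity, youden_j = best$j)
  })
  res$threshold <- cummax(res$threshold)
  res
}

# Exhaustive Youden sweep: candidate cut-points are midpoints between
# consecutive distinct scores plus the extremes; classify positive if
# score >= threshold. Ties on J resolve to the lowest threshold.
best_youden <- function(scores, pos) {
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  sens <- vapply(cand, function(th) mean(scores[pos] >= th), numeric(1))
  spec <- vapply(cand, function(th) mean(scores[!pos] < th), numeric(1))
  j <- sens + spec - 1
  i <- which.max(j)
  list(threshold = cand[i], sensitivity = sens[i], specificity = spec[i],
       j = j[i])
}

#' Activity-stratified AUC
#'
#' AUC within each activity stratum (sitting, walking, ...). A stratum in
#' which one class is absent is flagged rather than scored.
#'
#' @param data Data frame with columns `score`, `label` (logical or 0/1
#'   positive indicator) and `activity`.
#' @return A tibble with one row per activity: `activity`, `n_pos`, `n_neg`,
#'   `auc` (NA when flagged), `flag`.
#' @export
stratified_auc <- function(data) {
  stopifnot(all(c("score", "label", "activity") %in% names(data)))
  data |>
    dplyr::group_by(.data$activity) |>
    dplyr::summarise(
      n_pos = sum(as.logical(.data$label)),
      n_neg = sum(!as.logical(.data$label)),
      auc = if (sum(as.logical(.data$label)) > 0 &&
                sum(!as.logical(.data$label)) > 0) {
        auc_score(.data$score, .data$label)
      } else {
        NA_real_
      },
      .groups = "drop") |>
    dplyr::mutate(flag = ifelse(is.na(.data$auc), "missing class", ""))
}

#' Mean waveforms of the top-scoring windows
#'
#' Recovers the acceleration pattern the classifier responds to: all windows
#' in the data are scored with the model's expression, and for each k in
#' `k_list` the element-wise mean of the k highest-scoring 32-sample windows
#' is returned.
#'
#' @param model A [classifier_model()] (time mode) or a bare `cgp_genome`.
#' @param windows Window matrix (see [extract_windows()]), or a list of
#'   magnitude series to window and pool.
#' @param k_list Numbers of top windows to average.
#' @return A `window_pattern` tibble with columns `k`, `position` (1-32) and
#'   `mean_value`.
#' @export
top_window_pattern <- function(model, windows, k_list = c(10, 100, 1000)) {
  genome <- if (inherits(model, "classifier_model")) model$genome else model
  if (is.list(windows) && !is.matrix(windows)) {
    windows <- do.call(rbind, lapply(windows, extract_windows))
  }
  if (nrow(windows) < max(k_list)) {
    stop("insufficient windows: ", nrow(windows), " < ", max(k_list),
         call. = FALSE)
  }
  out <- cgp_evaluate_matrix(genome, windows)
  ord <- order(out, decreasing = TRUE)
  res <- purrr::map_dfr(k_list, function(k) {
    mv <- colMeans(windows[ord[seq_len(k)], , drop = FALSE])
    tibble::tibble(k = k, position = seq_len(ncol(windows)), mean_value = mv)
  })
  structure(res, class = c("window_pattern", class(res)))
}

#' @method autoplot window_pattern
#' @export
autoplot.window_pattern <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       y = .data$mean_value,
                                       colour = factor(.data$k))) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "window sample", y = "mean acceleration magnitude",
                  colour = "top k",
                  title = "Mean pattern of highest-scoring windows") +
    ggplot2::theme_minimal()
}

#' Classifier model container
#'
#' Bundles an evolved genome with its feature mode, optional per-grade score
#' thresholds (see [grade_thresholds()] and [fit_thresholds()]) and training
#' provenance.
#'
#' @param genome A `cgp_genome`.
#' @param feature_mode See [evolution_config()].
#' @param thresholds Optional tibble from [grade_thresholds()].
#' @param provenance Optional named list of training metadata.
#' @return A `classifier_model`.
#' @export
classifier_model <- function(genome, feature_mode = "time", thresholds = NULL,
                             provenance = list()) {
  if (!is.null(thresholds) && is.unsorted(thresholds$threshold)) {
    stop("thresholds must be non-decreasing across grade boundaries",
         call. = FALSE)
  }
  structure(list(genome = genome, feature_mode = feature_mode,
                 thresholds = thresholds, provenance = provenance),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat("<classifier_model> ", x$feature_mode, " mode; ",
      if (is.null(x$thresholds)) "uncalibrated" else
        paste0(nrow(x$thresholds), " grade thresholds"), "\n", sep = "")
  invisible(x)
}

#' @method glance classifier_model
#' @export
glance.classifier_model <- function(x, ...) {
  tibble::tibble(feature_mode = x$feature_mode,
                 n_active_nodes = length(active_nodes(x$genome)),
                 calibrated = !is.null(x$thresholds))
}

#' Calibrate a model's grade thresholds
#'
#' @param model A [classifier_model()].
#' @param scores_by_grade Data frame with `score` and `grade` columns.
#' @inheritParams grade_thresholds
#' @return The model with `thresholds` fitted.
#' @export
fit_thresholds <- function(model, scores_by_grade, boundaries = 1:4) {
  model$thresholds <- grade_thresholds(scores_by_grade, boundaries)
  model
}

# Band a score: highest boundary whose threshold it reaches, else 0.
score_to_band <- function(score, thresholds) {
  vapply(score, function(s) {
    hit <- thresholds$boundary[s >= thresholds$threshold]
    if (length(hit)) max(hit) else 0
  }, numeric(1))
}

#' 24-hour episode summary of a recording
#'
#' Cuts a recording into consecutive fixed-length epochs, scores each epoch
#' with the model (mean expression output over the epoch's windows), bands
#' epochs with the model's calibrated thresholds, and merges adjacent epochs
#' in the same band at grade >= 3 into dyskinesia episodes. Epochs inside
#' user-supplied sleep intervals are excluded from banding; no gap-bridging
#' is applied when merging.
#'
#' @param recording A `recording` object or data frame (see [magnitude()]).
#' @param model A calibrated [classifier_model()].
#' @param epoch_s Epoch length in seconds (default 60).
#' @param medication_times Optional numeric vector of medication times
#'   (seconds from recording start), kept as chart annotations.
#' @param sleep_intervals Optional two-column data frame (`start_s`, `end_s`)
#'   of sleep periods.
#' @return An `episode_timeline`: list with tibbles `epochs` (`start_s`,
#'   `end_s`, `score`, `band`, `asleep`) and `episodes` (`start_s`, `end_s`,
#'   `band`, `n_epochs`), plus the annotations.
#' @export
episode_summary <- function(recording, model, epoch_s = 60,
                            medication_times = NULL, sleep_intervals = NULL) {
  if (is.null(model$thresholds)) {
    stop("model not calibrated: fit thresholds before summarising episodes",
         call. = FALSE)
  }
  stopifnot(epoch_s >= 0.32)
  mag <- magnitude(recording)
  sr <- attr(mag, "sample_rate")
  if (is.null(sr)) sr <- 100
  x <- mag$magnitude
  samples_per_epoch <- as.integer(round(epoch_s * sr))
  n_epochs <- length(x) %/% samples_per_epoch
  if (n_epochs < 1) stop("recording shorter than one epoch", call. = FALSE)

  starts_s <- (seq_len(n_epochs) - 1) * epoch_s
  score <- vapply(seq_len(n_epochs), function(i) {
    seg <- x[((i - 1) * samples_per_epoch + 1):(i * samples_per_epoch)]
    segment_score(model$genome, seg, model$feature_mode, sample_rate = sr)
  }, numeric(1))
  asleep <- rep(FALSE, n_epochs)
  if (!is.null(sleep_intervals)) {
    for (r in seq_len(nrow(sleep_intervals))) {
      asleep <- asleep | (starts_s >= sleep_intervals$start_s[r] &
                          starts_s + epoch_s <= sleep_intervals$end_s[r])
    }
  }
  band <- score_to_band(score, model$thresholds)
  band[asleep] <- NA_real_

  epochs <- tibble::tibble(start_s = starts_s, end_s = starts_s + epoch_s,
                           score = score, band = band, asleep = asleep)
  key <- ifelse(is.na(band) | band < 3, 0, band)
  runs <- rle(key)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1
  sel <- runs$values >= 3
  episodes <- tibble::tibble(
    start_s = starts_s[run_start[sel]],
    end_s = starts_s[run_end[sel]] + epoch_s,
    band = runs$values[sel],
    n_epochs = runs$lengths[sel])

  structure(list(epochs = epochs, episodes = episodes,
                 medication_times = medication_times,
                 sleep_intervals = sleep_intervals, epoch_s = epoch_s),
            class = "episode_timeline")
}

#' @export
print.episode_timeline <- function(x, ...) {
  cat("<episode_timeline> ", nrow(x$epochs), " epochs of ", x$epoch_s,
      " s; ", nrow(x$episodes), " dyskinesia episode(s) at grade >= 3\n",
      sep = "")
  invisible(x)
}

#' @method tidy episode_timeline
#' @export
tidy.episode_timeline <- function(x, ...) x$epochs

#' @method glance episode_timeline
#' @export
glance.episode_timeline <- function(x, ...) {
  tibble::tibble(n_epochs = nrow(x$epochs),
                 n_episodes = nrow(x$episodes),
                 total_episode_s = sum(x$episodes$end_s - x$episodes$start_s),
                 grade4_episode_s = sum(
                   (x$episodes$end_s - x$episodes$start_s)[x$episodes$band == 4]))
}

#' Clinical summary chart of an episode timeline
#'
#' Mirrors the clinician-facing 24-hour chart: epoch scores as a line, grade-3
#' episodes in light green, grade-4 episodes in dark green, medication times
#' as red dots and sleep as a purple bar.
#'
#' @param object An `episode_timeline`.
#' @param ... Unused.
#' @method autoplot episode_timeline
#' @export
autoplot.episode_timeline <- function(object, ...) {
  ep <- object$epochs
  p <- ggplot2::ggplot(ep, ggplot2::aes(x = .data$start_s / 3600,
                                        y = .data$score)) +
    ggplot2::geom_line(colour = "grey40")
  if (nrow(object$episodes)) {
    p <- p + ggplot2::geom_rect(
      data = object$episodes,
      ggplot2::aes(xmin = .data$start_s / 3600, xmax = .data$end_s / 3600,
                   ymin = -Inf, ymax = Inf,
                   fill = factor(.data$band)),
      inherit.aes = FALSE, alpha = 0.35)
  }
  if (!is.null(object$sleep_intervals) && nrow(object$sleep_intervals)) {
    p <- p + ggplot2::geom_segment(
      data = object$sleep_intervals,
      ggplot2::aes(x = .data$start_s / 3600, xend = .data$end_s / 3600,
                   y = -Inf, yend = -Inf),
      inherit.aes = FALSE, colour = "purple", linewidth = 2)
  }
  if (!is.null(object$medication_times)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(t = object$medication_times),
      ggplot2::aes(x = .data$t / 3600, y = 0),
      inherit.aes = FALSE, colour = "red", size = 2)
  }
  p + ggplot2::scale_fill_manual(
        values = c(`3` = "palegreen3", `4` = "darkgreen"),
        name = "grade") +
    ggplot2::labs(x = "time (h)", y = "classifier score",
                  title = "Dyskinesia episode summary") +
    ggplot2::theme_minimal()
}

#' Phase-invariant waveform shape similarity
#'
#' Pearson correlation between two waveforms at their best alignment: one
#' waveform is slid against the other over lags up to `max_lag` samples and
#' the maximum correlation of the overlapping parts is returned. Used to
#' compare a recovered top-window mean with the planted burst template, whose
#' phase inside the 32-sample window frame is arbitrary.
#'
#' @param x,y Numeric waveforms of equal length.
#' @param max_lag Maximum alignment shift in samples (default 10).
#' @return Maximum correlation over lags, in \[-1, 1\].
#' @export
waveform_similarity <- function(x, y, max_lag = 10) {
  stopifnot(length(x) == length(y), length(x) > max_lag + 2)
  n <- length(x)
  best <- -1
  for (lag in -max_lag:max_lag) {
    if (lag >= 0) {
      a <- x[(1 + lag):n]
      b <- y[1:(n - lag)]
    } else {
      a <- x[1:(n + lag)]
      b <- y[(1 - lag):n]
    }
    r <- suppressWarnings(stats::cor(a, b))
    if (!is.na(r)) best <- max(best, r)
  }
  best
}
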