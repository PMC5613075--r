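#' Evolution configuration
#'
#' Parameters of the generational evolutionary algorithm used to train
#' classifier expressions. Defaults follow the training setup used for the
#' clinical classifiers: population 200, 100 generations, with tournament
#' selection (size 4), elitism of 1, per-gene mutation rate 0.02 and
#' crossover probability 0.9.
#'
#' @param population_size Number of genomes per generation (>= 2).
#' @param generations Number of generations to run (>= 1).
#' @param mutation_rate Per-gene mutation probability.
#' @param crossover_prob Probability a child is produced by crossover rather
#'   than cloning its first parent.
#' @param tournament_size Tournament size for parent selection.
#' @param elitism Number of best genomes copied unchanged each generation.
#' @param feature_mode `"time"` (raw 32-sample windows), `"spectral_long"`
#'   (one 32-bin long-term spectrum per segment) or `"spectral_short"`
#'   (32-bin spectrum of each window).
#' @param seed Integer seed fixing the whole run.
#' @param geometry CGP grid geometry.
#' @return An `evolution_config` list.
#' @export
evolution_config <- function(population_size = 200L, generations = 100L,
                             mutation_rate = 0.02, crossover_prob = 0.9,
                             tournament_size = 4L, elitism = 1L,
                             feature_mode = c("time", "spectral_long",
                                              "spectral_short"),
                             seed = 1L, geometry = cgp_geometry()) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(population_size >= 2, generations >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            tournament_size >= 1, elitism >= 0,
            elitism < population_size)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 crossover_prob = crossover_prob,
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism),
                 feature_mode = feature_mode,
                 seed = as.integer(seed),
                 geometry = geometry),
            class = "evolution_config")
}

#' Score a movement segment with a genome
#'
#' The per-segment classifier output: in time mode the expression is applied
#' to each of the L - 31 overlapping 32-sample windows of the magnitude
#' series and the segment score is the mean of those outputs ("the mean
#' occurrence of the movement pattern"); in spectral_short mode the
#' expression is applied to the 32-bin spectrum of each window and averaged;
#' in spectral_long mode it is applied once to the segment's 32 long-term
#' spectral densities.
#'
#' @param genome A `cgp_genome`.
#' @param series Magnitude series of the segment (numeric vector or
#'   magnitude tibble).
#' @param feature_mode See [evolution_config()].
#' @param sample_rate Samples per second (only used in spectral_long mode).
#' @return A single numeric score.
#' @export
segment_score <- function(genome, series,
                          feature_mode = c("time", "spectral_long",
                                           "spectral_short"),
                          sample_rate = 100) {
  feature_mode <- match.arg(feature_mode)
  x <- series_values(series)
  feats <- segment_features(x, feature_mode, sample_rate)
  mean(cgp_evaluate_matrix(genome, feats))
}

# Feature matrix of one segment under a feature mode. Time and
# spectral_short give one row per window; spectral_long a single row.
segment_features <- function(x, feature_mode, sample_rate = 100) {
  if (feature_mode == "spectral_long") {
    matrix(long_term_spectrum(x, sample_rate)$density, nrow = 1)
  } else {
    w <- tryCatch(extract_windows(x),
                  error = function(e) stop("no windows: ", conditionMessage(e),
                                           call. = FALSE))
    if (feature_mode == "time") w else short_term_spectra(w)
  }
}

# Precompute the stacked feature matrix of a training set once, so that each
# genome evaluation is a handful of vectorised operations over all rows.
build_features <- function(training_set, feature_mode, sample_rate = 100) {
  stopifnot(is.data.frame(training_set),
            all(c("grade", "series") %in% names(training_set)))
  mats <- lapply(training_set$series, segment_features,
                 feature_mode = feature_mode, sample_rate = sample_rate)
  list(X = do.call(rbind, mats),
       segment = rep(seq_len(nrow(training_set)),
                     vapply(mats, nrow, integer(1))),
       n_segments = nrow(training_set),
       grade = training_set$grade)
}

segment_scores_from_features <- function(genome, feats) {
  out <- cgp_evaluate_matrix(genome, feats$X)
  as.numeric(rowsum(out, feats$segment, reorder = TRUE)) /
    tabulate(feats$segment, feats$n_segments)
}

# Grades strictly between 0 and 3 (mild / ambiguous dyskinesia) are excluded
# from fitness; a rater-averaged 2.5 is out, 3.5 is in.
training_mask <- function(grade) grade == 0 | grade >= 3

#' Training fitness of a genome (AUC)
#'
#' Fitness is the AUC of per-segment scores discriminating clinically
#' significant dyskinesia (grade >= 3) from no dyskinesia (grade 0).
#' Segments with grades strictly between 0 and 3 are excluded: classifiers
#' train more robustly when the clinically ambiguous grades 1-2 are left
#' out.
#'
#' @param genome A `cgp_genome`.
#' @param training_set Tibble with columns `grade` (numeric 0-4, possibly
#'   fractional after rater averaging) and `series` (list column of
#'   magnitude series).
#' @param feature_mode See [evolution_config()].
#' @return AUC in \[0, 1\].
#' @export
fitness <- function(genome, training_set,
                    feature_mode = c("time", "spectral_long",
                                     "spectral_short")) {
  feature_mode <- match.arg(feature_mode)
  feats <- build_features(training_set, feature_mode)
  fitness_from_features(genome, feats)
}

fitness_from_features <- function(genome, feats) {
  keep <- training_mask(feats$grade)
  lab <- feats$grade[keep] >= 3
  if (!any(lab) || all(lab)) {
    stop("degenerate training set: need grade-0 and grade>=3 segments",
         call. = FALSE)
  }
  scores <- segment_scores_from_features(genome, feats)
  auc_score(scores[keep], lab)
}

#' Evolve a classifier genome
#'
#' Generational evolutionary algorithm: tournament selection, uniform
#' node-wise crossover with probability `crossover_prob`, per-gene point
#' mutation, and elitism. Fitness is the grade-0 vs grade>=3 AUC of
#' per-segment scores (see [fitness()]). The run is fully determined by
#' `config$seed`.
#'
#' @param training_set See [fitness()].
#' @param config An [evolution_config()].
#' @return A `cgp_run` object: `best_genome`, `best_fitness_history`
#'   (best-so-far training AUC at generation 0 .. generations), `config`,
#'   `seed`.
#' @export
evolve <- function(training_set, config = evolution_config()) {
  # only grade-0 and grade>=3 segments enter fitness; drop the rest up front
  training_set <- training_set[training_mask(training_set$grade), ]
  feats <- build_features(training_set, config$feature_mode)
  lab <- feats$grade >= 3
  if (!any(lab) || all(lab)) {
    stop("degenerate training set: need grade-0 and grade>=3 segments",
         call. = FALSE)
  }

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  pop <- replicate(config$population_size, random_genome(config$geometry),
                   simplify = FALSE)
  fit <- vapply(pop, fitness_from_features, numeric(1), feats = feats)
  history <- numeric(config$generations + 1L)
  history[1] <- max(fit)

  tournament <- function() {
    cand <- sample.int(config$population_size, config$tournament_size,
                       replace = TRUE)
    cand[which.max(fit[cand])]
  }

  for (gen in seq_len(config$generations)) {
    elite_idx <- order(fit, decreasing = TRUE)[seq_len(config$elitism)]
    new_pop <- pop[elite_idx]
    new_fit <- fit[elite_idx]
    while (length(new_pop) < config$population_size) {
      pa <- pop[[tournament()]]
      child <- if (stats::runif(1) < config$crossover_prob) {
        crossover_genomes(pa, pop[[tournament()]])
      } else {
        pa
      }
      child <- mutate_genome(child, config$mutation_rate)
      new_pop <- c(new_pop, list(child))
      new_fit <- c(new_fit, fitness_from_features(child, feats))
    }
    pop <- new_pop
    fit <- new_fit
    history[gen + 1L] <- max(history[gen], max(fit))
  }

  best <- which.max(fit)
  structure(list(best_genome = pop[[best]],
                 best_fitness = fit[best],
                 best_fitness_history = history,
                 config = config,
                 seed = config$seed),
            class = "cgp_run")
}

#' @export
print.cgp_run <- function(x, ...) {
  cat("<cgp_run> seed ", x$seed, ", ", x$config$feature_mode,
      " mode, final training AUC ",
      format(round(x$best_fitness, 4)), "\n", sep = "")
  invisible(x)
}

#' @method tidy cgp_run
#' @export
tidy.cgp_run <- function(x, ...) {
  tibble::tibble(generation = seq_along(x$best_fitness_history) - 1L,
                 best_fitness = x$best_fitness_history)
}

#' @method glance cgp_run
#' @export
glance.cgp_run <- function(x, ...) {
  tibble::tibble(seed = x$seed, feature_mode = x$config$feature_mode,
                 generations = x$config$generations,
                 population_size = x$config$population_size,
                 best_fitness = x$best_fitness)
}

#' Repeated independent trainings with test-set model selection
#'
#' Runs [evolve()] once per seed, scores each run's best genome on the test
#' split, and returns the genome with the highest test AUC as the deployment
#' model together with the full per-run AUC distribution (for box-plot
#' comparisons of classifier variants).
#'
#' @param training_set,test_set Segment tibbles (see [fitness()]).
#' @param config Base [evolution_config()]; its seed is replaced per run.
#' @param seeds Integer vector of distinct run seeds.
#' @return A `cgp_selection` list: `model` (a [classifier_model()]), `runs`
#'   (tibble with `seed`, `train_auc`, `test_auc`), `best_seed`.
#' @export
multi_run_select <- function(training_set, test_set,
                             config = evolution_config(), seeds = 1:10) {
  stopifnot(length(seeds) >= 1, !anyDuplicated(seeds))
  runs <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    evolve(training_set, cfg)
  })
  test_feats <- build_features(test_set, config$feature_mode)
  test_auc <- vapply(runs, function(r) {
    fitness_from_features(r$best_genome, test_feats)
  }, numeric(1))
  tab <- tibble::tibble(seed = as.integer(seeds),
                        train_auc = vapply(runs, `[[`, numeric(1),
                                           "best_fitness"),
                        test_auc = test_auc)
  best <- which.max(test_auc)
  model <- classifier_model(runs[[best]]$best_genome, config$feature_mode,
                            provenance = list(
                              selected_seed = as.integer(seeds[best]),
                              n_runs = length(seeds),
                              test_auc = test_auc[best]))
  structure(list(model = model, runs = tab,
                 best_seed = as.integer(seeds[best])),
            class = "cgp_selection")
}

#' @export
print.cgp_selection <- function(x, ...) {
  cat("<cgp_selection> ", nrow(x$runs), " run(s); best seed ", x$best_seed,
      " with test AUC ", format(round(max(x$runs$test_auc), 4)), "\n",
      sep = "")
  invisible(x)
}

#' @method tidy cgp_selection
#' @export
tidy.cgp_selection <- function(x, ...) x$runs

#' @method glance cgp_selection
#' @export
glance.cgp_selection <- function(x, ...) {
  tibble::tibble(n_runs = nrow(x$runs), best_seed = x$best_seed,
                 best_test_auc = max(x$runs$test_auc),
                 median_test_auc = stats::median(x$runs$test_auc))
}

#' Box-plot of the per-run test AUC distribution
#'
#' @param object A `cgp_selection`.
#' @param ... Unused.
#' @method autoplot cgp_selection
#' @export
autoplot.cgp_selection <- function(object, ...) {
  ggplot2::ggplot(object$runs, ggplot2::aes(x = "runs", y = .data$test_auc)) +
    ggplot2::geom_boxplot(notch = FALSE, width = 0.4) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "test AUC",
                  title = "Test AUC over independent runs") +
    ggplot2::theme_minimal()
}
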