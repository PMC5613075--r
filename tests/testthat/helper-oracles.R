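# Independent oracles used across the suite. These deliberately re-derive
# results by the most transparent route available (recursion, exhaustive
# enumeration, direct DFT sums) and share no code with the implementation.

# Recursive tree-walk interpreter for a CGP genome: evaluates the expression
# by recursion from the output gene, with its own primitive definitions.
oracle_eval <- function(genome, inputs) {
  g <- genome$geometry
  walk <- function(s) {
    if (s < g$n_inputs) {
      return(inputs[s + 1])
    }
    nd <- genome$nodes[s - g$n_inputs + 1, ]
    a <- walk(nd[["in_a"]])
    b <- walk(nd[["in_b"]])
    fn <- g$functions[nd[["fun"]] + 1]
    if (fn == "add") a + b
    else if (fn == "sub") a - b
    else if (fn == "mul") a * b
    else if (fn == "div") { if (abs(b) < 1e-6) a else a / b }
    else if (fn == "mean") (a + b) / 2
    else if (fn == "min") min(a, b)
    else if (fn == "max") max(a, b)
    else if (fn == "abs") abs(a)
    else stop("oracle: unknown function ", fn)
  }
  walk(genome$output)
}

# Breadth-first reachability over connection genes (phenotype oracle).
oracle_active <- function(genome) {
  n_in <- genome$geometry$n_inputs
  seen <- integer(0)
  frontier <- genome$output
  while (length(frontier)) {
    nodes <- unique(frontier[frontier >= n_in] - n_in + 1)
    nodes <- setdiff(nodes, seen)
    seen <- c(seen, nodes)
    frontier <- as.vector(genome$nodes[nodes, c("in_a", "in_b")])
  }
  sort(seen)
}

# Exhaustive pair-counting AUC.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# Direct DFT periodogram of a 32-sample window zero-padded to 64, matching
# the declared feature definition: p_k = 2|X_k|^2 / (64 * 32), Nyquist bin
# unmirrored, DC dropped.
oracle_short_spectrum <- function(window) {
  x <- c(window, rep(0, 32))
  n <- 64
  p <- numeric(32)
  for (k in 1:32) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    p[k] <- 2 * (re^2 + im^2) / (n * 32)
  }
  p[32] <- p[32] / 2
  p
}

# Exhaustive Youden scan over every achievable classification: thresholds at
# each observed score and +Inf, rule score >= threshold.
oracle_best_j <- function(scores, pos) {
  cand <- c(sort(unique(scores)), Inf)
  best <- -Inf
  for (th in cand) {
    sens <- mean(scores[pos] >= th)
    spec <- mean(scores[!pos] < th)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Matched filter against the planted template: peak sliding response of the
# centred unit-norm template (canonical detection statistic).
oracle_matched_filter <- function(series, template = caldera_template(32)) {
  tn <- (template - mean(template)) / sqrt(sum((template - mean(template))^2))
  w <- extract_windows(series, width = length(template))
  max(as.numeric((w - rowMeans(w)) %*% tn))
}

# Hand-built genome computing abs(x_i - x_j) (0-based terminal indices).
genome_abs_diff <- function(i = 0L, j = 1L, geometry = cgp_geometry()) {
  nodes <- matrix(0L, n_rows <- geometry$rows * geometry$cols, 3,
                  dimnames = list(NULL, c("fun", "in_a", "in_b")))
  nodes[, "fun"] <- 0L # unused nodes default to add(x0, x0)
  nodes[1, ] <- c(1L, as.integer(i), as.integer(j))          # sub in column 1
  abs_node <- geometry$rows + 1L                             # first of column 2
  nodes[abs_node, ] <- c(7L, geometry$n_inputs, 0L)          # abs(node 1)
  caldera:::new_cgp_genome(nodes, geometry$n_inputs + abs_node - 1L, geometry)
}

# A small, quick synthetic study for unit tests (full study conditions are
# exercised in the acceptance suite).
small_counts <- function() {
  tibble::tibble(
    split = rep(c("train", "test", "holdout"), each = 5),
    class = rep(c("rest", "walking", "voluntary", "dyskinesia", "dyskinesia"),
                3),
    grade = rep(c(0, 0, 0, 3, 4), 3),
    n = rep(c(3, 2, 2, 3, 3), 3))
}

small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_study(synthetic_config(counts = small_counts(),
                                                seed = 11L))
    }
    cache
  }
})

# Magnitude series of a generated segment's accelerometer channels.
magnitude_of <- function(seg) sqrt(rowSums(seg$accel^2))
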