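#' CGP grid geometry
#'
#' Fixed geometry of the Cartesian genetic programming genome: a 6 x 6 grid of
#' up to 36 function nodes drawn from the 8-function set
#' add, sub, mul, div, mean, min, max, abs, fed by 32 terminal inputs (the
#' samples of one sliding window, or 32 spectral densities). Nodes connect
#' feed-forward only: a node may read any terminal or any node in a strictly
#' earlier column (levels-back unlimited).
#'
#' @param rows,cols Grid dimensions (default 6 x 6).
#' @param n_inputs Number of terminal inputs (default 32).
#' @param functions Ordered character vector of function names.
#' @return A `cgp_geometry` object.
#' @export
cgp_geometry <- function(rows = 6L, cols = 6L, n_inputs = 32L,
                         functions = cgp_function_set()) {
  stopifnot(rows >= 1, cols >= 1, n_inputs >= 1,
            all(functions %in% cgp_function_set()))
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         n_inputs = as.integer(n_inputs), functions = functions),
    class = "cgp_geometry")
}

#' @rdname cgp_geometry
#' @export
cgp_function_set <- function() {
  c("add", "sub", "mul", "div", "mean", "min", "max", "abs")
}

n_nodes <- function(geometry) geometry$rows * geometry$cols

# Column (1-based) of node j (1-based, column-major layout).
node_column <- function(geometry, j) ((j - 1L) %/% geometry$rows) + 1L

# Legal source values (0-based) for a node in column `col`:
# terminals 0 .. n_inputs-1, plus nodes in strictly earlier columns.
legal_sources <- function(geometry, col) {
  n_in <- geometry$n_inputs
  terminals <- seq_len(n_in) - 1L
  if (col == 1L) return(terminals)
  earlier <- n_in + seq_len(geometry$rows * (col - 1L)) - 1L
  c(terminals, earlier)
}

#' Draw a uniformly random valid genome
#'
#' Every connection gene is drawn uniformly from its legal range (respecting
#' the feed-forward constraint), every function gene uniformly from the
#' function set, and the output gene uniformly over all terminals and nodes.
#' Uses R's RNG stream; seed it for reproducibility.
#'
#' @param geometry A [cgp_geometry()].
#' @return A `cgp_genome`: integer node matrix (columns `fun`, `in_a`,
#'   `in_b`; sources 0-based, terminals first) plus an `output` gene.
#' @export
random_genome <- function(geometry = cgp_geometry()) {
  nn <- n_nodes(geometry)
  nodes <- matrix(0L, nrow = nn, ncol = 3,
                  dimnames = list(NULL, c("fun", "in_a", "in_b")))
  for (j in seq_len(nn)) {
    src <- legal_sources(geometry, node_column(geometry, j))
    nodes[j, ] <- c(sample.int(length(geometry$functions), 1L) - 1L,
                    src[sample.int(length(src), 1L)],
                    src[sample.int(length(src), 1L)])
  }
  output <- sample.int(geometry$n_inputs + nn, 1L) - 1L
  new_cgp_genome(nodes, output, geometry)
}

new_cgp_genome <- function(nodes, output, geometry) {
  structure(list(nodes = nodes, output = as.integer(output),
                 geometry = geometry),
            class = "cgp_genome")
}

#' @export
print.cgp_genome <- function(x, ...) {
  act <- active_nodes(x)
  cat("<cgp_genome> ", x$geometry$rows, "x", x$geometry$cols, " grid, ",
      x$geometry$n_inputs, " inputs, ", length(act), " active node(s)\n",
      sep = "")
  invisible(x)
}

validate_genome <- function(genome) {
  g <- genome$geometry
  nn <- n_nodes(g)
  nodes <- genome$nodes
  if (!is.matrix(nodes) || nrow(nodes) != nn || ncol(nodes) != 3) {
    stop("malformed genome: bad node matrix", call. = FALSE)
  }
  for (j in seq_len(nn)) {
    src <- legal_sources(g, node_column(g, j))
    if (!(nodes[j, "fun"] %in% (seq_along(g$functions) - 1L)) ||
        !(nodes[j, "in_a"] %in% src) || !(nodes[j, "in_b"] %in% src)) {
      stop("malformed genome: illegal gene at node ", j, call. = FALSE)
    }
  }
  if (genome$output < 0L || genome$output >= g$n_inputs + nn) {
    stop("malformed genome: illegal output gene", call. = FALSE)
  }
  invisible(genome)
}

#' Active nodes of a genome
#'
#' Decodes the phenotype: the set of nodes actually reachable from the output
#' gene, in topological (ascending index) order. Nodes outside this set are
#' inactive and carry neutral genetic variation.
#'
#' @param genome A `cgp_genome`.
#' @return Integer vector of active node indices (1-based), possibly empty.
#' @export
active_nodes <- function(genome) {
  g <- genome$geometry
  n_in <- g$n_inputs
  nn <- n_nodes(g)
  needed <- logical(nn)
  stack <- genome$output
  while (length(stack)) {
    s <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (s >= n_in) {
      j <- s - n_in + 1L
      if (j < 1L || j > nn) stop("malformed genome: source ", s, call. = FALSE)
      if (!needed[j]) {
        needed[j] <- TRUE
        stack <- c(stack, genome$nodes[j, "in_a"], genome$nodes[j, "in_b"])
      }
    }
  }
  which(needed)
}

#' Apply one primitive function
#'
#' The 8 primitives are total over finite inputs: division is protected,
#' returning the numerator when the denominator's magnitude is below 1e-6,
#' so evaluation can never produce Inf or NaN. `abs` ignores its second
#' argument; `mean` is the two-argument mean (a + b) / 2.
#'
#' @param fun Function name or 0-based index into [cgp_function_set()].
#' @param a,b Numeric vectors (recycled as usual).
#' @return Numeric vector.
#' @export
apply_function <- function(fun, a, b) {
  if (is.numeric(fun)) fun <- cgp_function_set()[fun + 1L]
  switch(fun,
    add  = a + b,
    sub  = a - b,
    mul  = a * b,
    div  = ifelse(abs(b) < 1e-6, a, a / b),
    mean = (a + b) / 2,
    min  = pmin(a, b),
    max  = pmax(a, b),
    abs  = abs(a),
    stop("unknown function: ", fun, call. = FALSE))
}

#' Evaluate a genome on one input vector
#'
#' @param genome A `cgp_genome`.
#' @param inputs Numeric vector of exactly `n_inputs` finite values (one
#'   sliding window, or one spectral density vector).
#' @return The scalar output of the decoded expression.
#' @export
cgp_evaluate <- function(genome, inputs) {
  if (length(inputs) != genome$geometry$n_inputs) {
    stop("arity mismatch: expected ", genome$geometry$n_inputs,
         " inputs, got ", length(inputs), call. = FALSE)
  }
  cgp_evaluate_matrix(genome, matrix(as.numeric(inputs), nrow = 1))[1]
}

#' Evaluate a genome over every row of an input matrix
#'
#' Vectorised evaluation: only active nodes are computed, each as one
#' vectorised operation over all rows. Identical results to evaluating rows
#' one at a time.
#'
#' @param genome A `cgp_genome`.
#' @param X Numeric matrix with `n_inputs` columns (e.g. a window matrix).
#' @return Numeric vector with one output per row of `X`.
#' @export
cgp_evaluate_matrix <- function(genome, X) {
  g <- genome$geometry
  n_in <- g$n_inputs
  if (ncol(X) != n_in) {
    stop("arity mismatch: expected ", n_in, " inputs, got ", ncol(X),
         call. = FALSE)
  }
  vals <- vector("list", n_in + n_nodes(g))
  src_val <- function(s) {
    if (s < n_in) X[, s + 1L] else vals[[s + 1L]]
  }
  for (j in active_nodes(genome)) {
    nd <- genome$nodes[j, ]
    vals[[n_in + j]] <- apply_function(nd[["fun"]], src_val(nd[["in_a"]]),
                                       src_val(nd[["in_b"]]))
  }
  out <- src_val(genome$output)
  if (length(out) == 1L && nrow(X) > 1L) out <- rep(out, nrow(X))
  as.numeric(out)
}

#' Point mutation
#'
#' Each gene (3 per node plus the output gene) is independently resampled
#' from its full legal range with probability `rate`; resampling may redraw
#' the current value. The feed-forward constraint is preserved by
#' construction and the parent is left unmodified.
#'
#' @param genome Parent genome.
#' @param rate Per-gene mutation probability in \[0, 1\] (default 0.02).
#' @return A new `cgp_genome`.
#' @export
mutate_genome <- function(genome, rate = 0.02) {
  stopifnot(rate >= 0, rate <= 1)
  g <- genome$geometry
  nn <- n_nodes(g)
  nodes <- genome$nodes
  hit <- matrix(stats::runif(nn * 3) < rate, nrow = nn)
  for (j in which(rowSums(hit) > 0)) {
    src <- legal_sources(g, node_column(g, j))
    if (hit[j, 1]) nodes[j, "fun"] <- sample.int(length(g$functions), 1L) - 1L
    if (hit[j, 2]) nodes[j, "in_a"] <- src[sample.int(length(src), 1L)]
    if (hit[j, 3]) nodes[j, "in_b"] <- src[sample.int(length(src), 1L)]
  }
  output <- genome$output
  if (stats::runif(1) < rate) output <- sample.int(g$n_inputs + nn, 1L) - 1L
  new_cgp_genome(nodes, output, g)
}

#' Uniform node-wise crossover
#'
#' Each of the 36 node triples is inherited wholly from one parent, chosen
#' with equal probability, as is the output gene. Both parents must share a
#' geometry, which guarantees the child is feed-forward valid.
#'
#' @param parent_a,parent_b Genomes with identical geometry.
#' @return A child `cgp_genome`.
#' @export
crossover_genomes <- function(parent_a, parent_b) {
  if (!identical(parent_a$geometry, parent_b$geometry)) {
    stop("incompatible parents: geometries differ", call. = FALSE)
  }
  nn <- n_nodes(parent_a$geometry)
  from_a <- stats::runif(nn) < 0.5
  nodes <- parent_a$nodes
  nodes[!from_a, ] <- parent_b$nodes[!from_a, , drop = FALSE]
  output <- if (stats::runif(1) < 0.5) parent_a$output else parent_b$output
  new_cgp_genome(nodes, output, parent_a$geometry)
}

#' Serialise / deserialise a genome as JSON
#'
#' Function genes are written by name so files remain readable if the
#' function-set ordering ever changes. Round-tripping is exact.
#'
#' @param genome A `cgp_genome`.
#' @return `genome_to_json()`: a JSON string. `genome_from_json()`: a
#'   `cgp_genome`.
#' @export
genome_to_json <- function(genome) {
  g <- genome$geometry
  jsonlite::toJSON(list(
    geometry = list(rows = g$rows, cols = g$cols, n_inputs = g$n_inputs,
                    functions = g$functions),
    nodes = lapply(seq_len(nrow(genome$nodes)), function(j) {
      nd <- genome$nodes[j, ]
      list(g$functions[nd[["fun"]] + 1L], nd[["in_a"]], nd[["in_b"]])
    }),
    output = genome$output
  ), auto_unbox = TRUE)
}

#' @rdname genome_to_json
#' @param json JSON string or parsed list as produced by `genome_to_json()`.
#' @export
genome_from_json <- function(json) {
  obj <- if (is.character(json)) jsonlite::fromJSON(json, simplifyVector = FALSE) else json
  geom <- cgp_geometry(obj$geometry$rows, obj$geometry$cols,
                       obj$geometry$n_inputs,
                       unlist(obj$geometry$functions))
  nodes <- t(vapply(obj$nodes, function(nd) {
    fid <- match(nd[[1]], geom$functions) - 1L
    if (is.na(fid)) stop("incompatible model file: unknown function ", nd[[1]],
                         call. = FALSE)
    c(fid, as.integer(nd[[2]]), as.integer(nd[[3]]))
  }, integer(3)))
  colnames(nodes) <- c("fun", "in_a", "in_b")
  validate_genome(new_cgp_genome(nodes, as.integer(obj$output), geom))
}
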