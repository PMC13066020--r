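# Ensemble simulation: configs, the compiled-rule bridge to the C++ core,
# and the ensemble_result container.

# compile a rule tree to postfix bytecode over node indices (0-based)
compile_rule <- function(rule, index) {
  switch(rule$op,
    const = if (rule$value) -2L else -1L,
    var = index[[rule$name]],
    not = c(compile_rule(rule$args[[1L]], index), -3L),
    and = {
      out <- compile_rule(rule$args[[1L]], index)
      for (a in rule$args[-1L]) out <- c(out, compile_rule(a, index), -4L)
      out
    },
    or = {
      out <- compile_rule(rule$args[[1L]], index)
      for (a in rule$args[-1L]) out <- c(out, compile_rule(a, index), -5L)
      out
    }
  )
}

compile_network <- function(network) {
  nms <- network$node_names
  index <- stats::setNames(seq_along(nms) - 1L, nms)
  progs <- lapply(network$rules, compile_rule, index = index)
  lens <- vapply(progs, length, 1L)
  list(prog = as.integer(unlist(progs)),
       prog_start = as.integer(c(0L, cumsum(lens))))
}

#' Initial-condition specification
#'
#' Each repetition initializes every node ON independently with the given
#' probability: an explicit per-node probability when listed, otherwise
#' `default_probability`. The default of 0.5 reflects a fair random ON/OFF
#' draw for unconstrained nodes.
#'
#' @param probabilities named numeric vector of per-node ON probabilities in
#'   \[0,1\].
#' @param default_probability probability for nodes not listed.
#' @return an object of class `initial_condition_spec`.
#' @export
initial_condition_spec <- function(probabilities = numeric(), default_probability = 0.5) {
  if (length(probabilities) > 0L && (is.null(names(probabilities)) || any(names(probabilities) == "")))
    stop("probabilities must be a named vector")
  if (any(c(probabilities, default_probability) < 0 | c(probabilities, default_probability) > 1))
    stop("initial probabilities must lie in [0,1]")
  structure(list(probabilities = probabilities, default_probability = default_probability),
            class = "initial_condition_spec")
}

#' Simulation configuration
#'
#' @param steps number of update steps (>= 1).
#' @param repetitions number of independent Monte-Carlo repetitions; the published protocol uses 5000, which
#'   gives activation-frequency standard errors below 0.008.
#' @param seed master integer seed; per-repetition substreams are derived
#'   deterministically from it, so identical `(network, config)` pairs give
#'   bit-identical results.
#' @param initial an [initial_condition_spec()].
#' @param perturbations list of [perturbation()] clamps.
#' @param measurement_window number of final steps over which end-state
#'   marginals are averaged; defaults to `min(50, steps)`. A window of 1
#'   reads the literal final step.
#' @param update_scheme `"permutation"`: one step applies a uniformly random
#'   permutation of all nodes sequentially against the evolving state (the
#'   default; several nodes may switch within one step). `"single"`: one
#'   uniformly random node per step, for sensitivity analysis.
#' @param evolving evaluate rules against the evolving within-step state
#'   (default) or against a frozen start-of-step snapshot.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(steps, repetitions = 5000, seed = 1,
                              initial = initial_condition_spec(),
                              perturbations = list(),
                              measurement_window = NULL,
                              update_scheme = c("permutation", "single"),
                              evolving = TRUE) {
  update_scheme <- match.arg(update_scheme)
  if (steps < 1) stop("steps must be >= 1")
  if (repetitions < 1) stop("repetitions must be >= 1")
  if (is.null(measurement_window)) measurement_window <- min(50L, steps)
  if (measurement_window < 1 || measurement_window > steps)
    stop("measurement_window must lie in [1, steps]")
  stopifnot(inherits(initial, "initial_condition_spec"))
  structure(list(steps = as.integer(steps), repetitions = as.integer(repetitions),
                 seed = as.integer(seed), initial = initial,
                 perturbations = perturbations,
                 measurement_window = as.integer(measurement_window),
                 update_scheme = update_scheme, evolving = isTRUE(evolving)),
            class = "simulation_config")
}

#' Stochastic update of one node (reference semantics)
#'
#' If the node's rule evaluates OFF the node switches OFF; if it evaluates ON
#' the node switches ON with probability equal to its polymorphism, else OFF.
#' Uses R's RNG stream; the ensemble engine implements the same semantics in
#' compiled code with its own substreams.
#'
#' @param rule a `rule_expr`.
#' @param state named logical vector (complete for the rule's leaves).
#' @param polymorphism activation probability in \[0,1\].
#' @return logical scalar, the node's next state.
#' @export
update_node <- function(rule, state, polymorphism = 1) {
  if (!evaluate_rule(rule, state)) return(FALSE)
  if (polymorphism >= 1) return(TRUE)
  stats::runif(1) < polymorphism
}

#' One asynchronous time step (reference semantics)
#'
#' Draws a uniformly random permutation of all nodes and updates them
#' sequentially against the evolving state. Clamped nodes take their clamped
#' value unconditionally. Uses R's RNG stream; intended for unit-scale tests
#' and illustration, not for large ensembles.
#'
#' @param state named logical vector.
#' @param network a [boolean_network()].
#' @param clamps named logical vector of currently active clamp values
#'   (may be empty).
#' @return the next state (named logical vector).
#' @export
simulate_step <- function(state, network, clamps = logical()) {
  nms <- network$node_names
  ord <- sample(nms)
  for (nm in ord) {
    if (nm %in% names(clamps)) {
      state[[nm]] <- clamps[[nm]]
    } else {
      state[[nm]] <- update_node(network$rules[[nm]], state, network$polymorphisms[[nm]])
    }
  }
  state[nms]
}

#' Run a Monte-Carlo ensemble of stochastic Boolean trajectories
#'
#' Simulates `repetitions` independent trajectories and records, for every
#' node and time step, the activation frequency: the fraction of repetitions
#' in which the node is ON at that step. End-state marginals are the mean
#' activation frequency over the final `measurement_window` steps.
#'
#' @param network a [boolean_network()].
#' @param config a [simulation_config()].
#' @return an object of class `ensemble_result` with elements:
#'   \describe{
#'     \item{frequency}{numeric matrix, nodes x (steps + 1); column `t`
#'       holds the frequency after update step `t`, column 0 the initial
#'       frequencies.}
#'     \item{end_marginals}{named numeric vector of window-averaged final
#'       activation frequencies.}
#'     \item{config, seed}{echo of the configuration.}
#'   }
#' @export
run_ensemble <- function(network, config) {
  stopifnot(inherits(network, "boolean_network"), inherits(config, "simulation_config"))
  nms <- network$node_names
  validate_perturbations(config$perturbations, nms)
  bad <- setdiff(names(config$initial$probabilities), nms)
  if (length(bad) > 0L) stop("initial condition names unknown node(s): ", paste(bad, collapse = ", "))

  init_prob <- rep(config$initial$default_probability, length(nms))
  names(init_prob) <- nms
  if (length(config$initial$probabilities) > 0L)
    init_prob[names(config$initial$probabilities)] <- config$initial$probabilities

  comp <- compile_network(network)
  np <- length(config$perturbations)
  clamp_node <- integer(np); clamp_value <- integer(np)
  clamp_start <- numeric(np); clamp_end <- numeric(np)
  for (k in seq_len(np)) {
    p <- config$perturbations[[k]]
    clamp_node[k] <- match(p$node, nms) - 1L
    clamp_value[k] <- if (p$mode == "FIX_ON") 1L else 0L
    clamp_start[k] <- p$start_step
    clamp_end[k] <- p$end_step
  }

  freq <- .simulate_ensemble_cpp(comp$prog, comp$prog_start,
                                 unname(network$polymorphisms), unname(init_prob),
                                 config$steps, config$repetitions,
                                 as.double(config$seed),
                                 clamp_node, clamp_value, clamp_start, clamp_end,
                                 config$evolving,
                                 if (config$update_scheme == "permutation") 0L else 1L)
  dimnames(freq) <- list(nms, as.character(0:config$steps))
  w <- config$measurement_window
  cols <- (config$steps - w + 1L):config$steps + 1L # matrix columns for steps steps-w+1 .. steps
  end_marginals <- rowMeans(freq[, cols, drop = FALSE])
  structure(list(frequency = freq, end_marginals = end_marginals,
                 config = config, seed = config$seed),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("ensemble_result:", nrow(x$frequency), "nodes,",
      ncol(x$frequency) - 1L, "steps,", x$config$repetitions, "repetitions\n")
  top <- sort(x$end_marginals, decreasing = TRUE)
  top <- utils::head(top, 5L)
  cat("  highest end marginals:",
      paste(sprintf("%s=%.2f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy per-step activation frequencies
#'
#' @param x an `ensemble_result`.
#' @param ... unused.
#' @return data.frame with columns `node`, `step`, `frequency`.
#' @export
as.data.frame.ensemble_result <- function(x, ...) {
  f <- x$frequency
  data.frame(node = rep(rownames(f), times = ncol(f)),
             step = rep(as.integer(colnames(f)), each = nrow(f)),
             frequency = as.vector(f),
             stringsAsFactors = FALSE)
}

#' Export an ensemble result
#'
#' `write_ensemble_csv()` writes tidy per-step frequencies
#' (columns node, step, frequency); `write_ensemble_json()` writes a summary
#' with end-state marginals, configuration and seed.
#'
#' @param result an `ensemble_result`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_ensemble_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
write_ensemble_json <- function(result, path) {
  cfg <- result$config
  out <- list(end_marginals = as.list(round(result$end_marginals, 4)),
              config = list(steps = cfg$steps, repetitions = cfg$repetitions,
                            measurement_window = cfg$measurement_window,
                            update_scheme = cfg$update_scheme,
                            evolving = cfg$evolving),
              seed = result$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
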