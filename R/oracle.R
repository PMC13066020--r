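# Exact Markov-chain oracle for small networks, plus a random toy-network
# generator. Everything here is pure R and shares no code with the compiled
# ensemble engine, so the two can check each other.

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in permutations_of(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# dense one-node transition factor over the 2^n state space
node_factor <- function(j, n_states, bit, truth, poly, clamp) {
  T <- matrix(0, n_states, n_states)
  s <- seq_len(n_states) - 1L
  on_target <- bitwOr(s, bit) + 1L
  off_target <- bitwAnd(s, bitwNot(bit)) + 1L
  if (!is.na(clamp)) {
    tgt <- if (clamp == 1) on_target else off_target
    T[cbind(seq_len(n_states), tgt)] <- 1
    return(T)
  }
  sat <- truth
  idx <- seq_len(n_states)
  # unsatisfied rows: all mass to OFF
  T[cbind(idx[!sat], off_target[!sat])] <- T[cbind(idx[!sat], off_target[!sat])] + 1
  # satisfied rows: ON with probability poly, OFF otherwise
  if (any(sat)) {
    T[cbind(idx[sat], on_target[sat])] <- T[cbind(idx[sat], on_target[sat])] + poly
    if (poly < 1)
      T[cbind(idx[sat], off_target[sat])] <- T[cbind(idx[sat], off_target[sat])] + (1 - poly)
  }
  T
}

#' Exact one-step transition matrix of the stochastic update process
#'
#' Enumerates the full 2^n state space and computes, for every ordered pair
#' of states, the probability of the one-step transition under the
#' permutation update scheme: the product of per-node update factors along a
#' node permutation, marginalized over permutations (exactly for
#' `n <= exact_limit`, by Monte-Carlo sampling of permutations above that,
#' with the sampling standard error reported in `perm_error`). Polymorphism
#' randomness and clamps are folded into the per-node factors; clamps are
#' treated as active at every step.
#'
#' @param network a [boolean_network()] with at most 12 nodes.
#' @param perturbations list of [perturbation()]; windows are ignored, a
#'   clamp listed here holds at every step of the chain.
#' @param initial an [initial_condition_spec()] defining the step-0
#'   distribution.
#' @param exact_limit largest node count for which all n! permutations are
#'   enumerated.
#' @param n_perm_samples number of sampled permutations above `exact_limit`.
#' @param seed seed for permutation sampling.
#' @return an object of class `exact_chain`: `transition` (2^n x 2^n, rows
#'   sum to 1), `initial` (length 2^n), `node_names`, `perm_error` (NA when
#'   exact).
#' @export
build_transition_matrix <- function(network, perturbations = list(),
                                    initial = initial_condition_spec(),
                                    exact_limit = 6L, n_perm_samples = 5000L,
                                    seed = 1L) {
  stopifnot(inherits(network, "boolean_network"))
  nms <- network$node_names
  n <- length(nms)
  if (n > 12L) stop("network too large for exact enumeration (", n, " nodes > 12)")
  validate_perturbations(perturbations, nms)
  n_states <- 2L^n
  s <- seq_len(n_states) - 1L

  # truth table per node via the R rule evaluator
  state_mat <- matrix(FALSE, n_states, n)
  for (i in seq_len(n)) state_mat[, i] <- bitwAnd(s, bitwShiftL(1L, i - 1L)) > 0L
  colnames(state_mat) <- nms
  truth <- matrix(FALSE, n_states, n)
  for (i in seq_len(n)) {
    rule <- network$rules[[i]]
    truth[, i] <- apply(state_mat, 1L, function(row) evaluate_rule(rule, as.list(row)))
  }

  clamp <- rep(NA_integer_, n)
  for (p in perturbations) clamp[match(p$node, nms)] <- if (p$mode == "FIX_ON") 1L else 0L

  factors <- lapply(seq_len(n), function(i) {
    node_factor(i, n_states, bitwShiftL(1L, i - 1L), truth[, i],
                network$polymorphisms[[i]], clamp[[i]])
  })

  perm_product <- function(perm) {
    M <- factors[[perm[[1L]]]]
    for (k in perm[-1L]) M <- M %*% factors[[k]]
    M
  }

  if (n <= exact_limit) {
    perms <- permutations_of(n)
    P <- matrix(0, n_states, n_states)
    for (pm in perms) P <- P + perm_product(pm)
    P <- P / length(perms)
    perm_error <- NA_real_
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    P <- matrix(0, n_states, n_states)
    sumsq <- 0
    for (m in seq_len(n_perm_samples)) {
      M <- perm_product(sample.int(n))
      P <- P + M
      sumsq <- sumsq + max(M)^2
    }
    P <- P / n_perm_samples
    # conservative entrywise Monte-Carlo standard error bound
    perm_error <- 0.5 / sqrt(n_perm_samples)
  }

  # initial distribution: independent product over nodes
  ip <- rep(initial$default_probability, n)
  names(ip) <- nms
  if (length(initial$probabilities) > 0L) ip[names(initial$probabilities)] <- initial$probabilities
  dist <- rep(1, n_states)
  for (i in seq_len(n)) {
    bit_on <- state_mat[, i]
    dist <- dist * ifelse(bit_on, ip[[i]], 1 - ip[[i]])
  }

  structure(list(transition = P, initial = dist, node_names = nms,
                 perm_error = perm_error),
            class = "exact_chain")
}

#' Exact per-node marginals after a number of steps
#'
#' Propagates the chain's initial distribution `step` times through the
#' transition matrix and sums state probabilities per node.
#'
#' @param chain an `exact_chain` from [build_transition_matrix()].
#' @param step non-negative integer; 0 returns the initial marginals.
#' @return named numeric vector of P(node = ON) at the given step.
#' @export
exact_marginals <- function(chain, step) {
  stopifnot(inherits(chain, "exact_chain"), step >= 0)
  dist <- chain$initial
  if (step > 0) for (t in seq_len(step)) dist <- as.vector(dist %*% chain$transition)
  marginals_from_dist(chain, dist)
}

marginals_from_dist <- function(chain, dist) {
  n <- length(chain$node_names)
  s <- seq_along(dist) - 1L
  out <- vapply(seq_len(n), function(i) sum(dist[bitwAnd(s, bitwShiftL(1L, i - 1L)) > 0L]), 0)
  names(out) <- chain$node_names
  out
}

#' Stationary distribution of an exact chain
#'
#' Left eigenvector of the transition matrix for eigenvalue 1 (power
#' iteration refined from the eigen decomposition); useful for long-run
#' comparisons against engine marginals.
#'
#' @param chain an `exact_chain`.
#' @return named numeric vector of stationary per-node marginals.
#' @export
stationary_marginals <- function(chain) {
  e <- eigen(t(chain$transition))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v <- v / sum(v)
  marginals_from_dist(chain, v)
}

#' Generate a random small Boolean network
#'
#' Random rules over sampled regulators combined with AND/OR and leaf-level
#' negation; nodes with no regulators get constant TRUE/FALSE rules.
#' Polymorphisms are drawn uniformly from `polymorphism_range`. Reproducible
#' from `seed` (R's RNG state is saved and restored). Generated networks
#' round-trip through [write_rule_file()] / [parse_rule_file()].
#'
#' @param n_nodes number of nodes (2..12).
#' @param edge_density probability that any given node regulates another;
#'   0 yields all-constant rules.
#' @param polymorphism_range length-2 numeric range for sampled activation
#'   probabilities; `c(1, 1)` gives a deterministic network.
#' @param seed integer seed.
#' @return a [boolean_network()].
#' @export
generate_toy_network <- function(n_nodes, edge_density = 0.4,
                                 polymorphism_range = c(0.5, 1), seed = 1L) {
  if (n_nodes < 2L || n_nodes > 12L) stop("n_nodes must lie in 2..12")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  nms <- paste0("N", seq_len(n_nodes))
  rules <- list()
  for (i in seq_len(n_nodes)) {
    k <- stats::rbinom(1L, n_nodes, edge_density)
    if (k == 0L) {
      rules[[nms[[i]]]] <- rule_const(stats::runif(1) < 0.5)
      next
    }
    regs <- sample(nms, k)
    leaves <- lapply(regs, function(r) {
      v <- rule_var(r)
      if (stats::runif(1) < 0.3) rule_not(v) else v
    })
    expr <- leaves[[1L]]
    if (k > 1L) {
      for (j in 2:k) {
        expr <- if (stats::runif(1) < 0.5) rule_and(expr, leaves[[j]]) else rule_or(expr, leaves[[j]])
      }
    }
    rules[[nms[[i]]]] <- expr
  }
  poly <- stats::runif(n_nodes, polymorphism_range[[1L]], polymorphism_range[[2L]])
  names(poly) <- nms
  boolean_network(rules, poly, metadata = list(name = sprintf("toy-%d-node", n_nodes),
                                               seed = seed))
}
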