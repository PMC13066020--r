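# Boolean network container, perturbations (clamps), and the signed
# influence graph extracted from rule syntax.

#' Boolean network with per-node activation probabilities
#'
#' A network is an ordered collection of nodes, each with a logic rule and a
#' polymorphism: the probability that the node actually switches ON in an
#' update where its rule is satisfied (1 = deterministic activation).
#'
#' @param rules named list of `rule_expr` objects, one per node, in
#'   declaration order.
#' @param polymorphisms named numeric vector of activation probabilities in
#'   \[0,1\]; nodes absent from the vector default to 1.
#' @param metadata free-form provenance list.
#' @return an object of class `boolean_network` with elements `node_names`,
#'   `rules`, `polymorphisms`, `metadata`.
#' @export
boolean_network <- function(rules, polymorphisms = NULL, metadata = list()) {
  nms <- names(rules)
  if (is.null(nms) || anyDuplicated(nms)) stop("rules must be uniquely named")
  p <- rep(1, length(nms))
  names(p) <- nms
  if (!is.null(polymorphisms)) {
    bad <- setdiff(names(polymorphisms), nms)
    if (length(bad) > 0L) stop("polymorphism for undeclared node(s): ", paste(bad, collapse = ", "))
    if (any(polymorphisms < 0 | polymorphisms > 1)) stop("polymorphisms must lie in [0,1]")
    p[names(polymorphisms)] <- polymorphisms
  }
  refs <- unique(unlist(lapply(rules, rule_leaves)))
  unknown <- setdiff(refs, nms)
  if (length(unknown) > 0L) {
    stop("rules reference undeclared node(s): ", paste(sort(unknown), collapse = ", "))
  }
  structure(list(node_names = nms, rules = rules, polymorphisms = p, metadata = metadata),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network:", length(x$node_names), "nodes\n")
  np <- sum(x$polymorphisms < 1)
  if (np > 0L) cat("  ", np, "node(s) with polymorphism < 1\n")
  if (!is.null(x$metadata$name)) cat("  name:", x$metadata$name, "\n")
  invisible(x)
}

#' Set node polymorphisms
#'
#' @param network a [boolean_network()].
#' @param values named numeric vector of activation probabilities in \[0,1\].
#' @return the modified network.
#' @export
set_polymorphisms <- function(network, values) {
  stopifnot(inherits(network, "boolean_network"))
  bad <- setdiff(names(values), network$node_names)
  if (length(bad) > 0L) stop("unknown node(s): ", paste(bad, collapse = ", "))
  if (any(values < 0 | values > 1)) stop("polymorphisms must lie in [0,1]")
  network$polymorphisms[names(values)] <- values
  network
}

# ---- perturbations ---------------------------------------------------------

#' Clamp a node ON or OFF for a window of time steps
#'
#' A perturbation fixes a node in the requested state during
#' `[start_step, end_step)`, overriding both its rule and its polymorphism.
#' Used for loss-of-function mutations (`FIX_OFF`), gain-of-function
#' mutations and sustained stimuli (`FIX_ON`), and in-silico knockouts.
#'
#' @param node node name.
#' @param mode `"FIX_ON"` or `"FIX_OFF"`.
#' @param start_step first step (>= 1) at which the clamp is active; the
#'   initial state (step 0) is governed by the initial-condition spec.
#' @param end_step first step at which the clamp is no longer active;
#'   `Inf` (default) clamps for the remainder of the simulation.
#' @return an object of class `perturbation`.
#' @export
perturbation <- function(node, mode = c("FIX_OFF", "FIX_ON"), start_step = 1, end_step = Inf) {
  mode <- match.arg(mode)
  if (start_step < 0) stop("start_step must be >= 0")
  if (end_step <= start_step) stop("empty clamp window")
  structure(list(node = node, mode = mode, start_step = start_step, end_step = end_step),
            class = "perturbation")
}

validate_perturbations <- function(perturbations, node_names) {
  for (p in perturbations) {
    if (!inherits(p, "perturbation")) stop("perturbations must be perturbation objects")
    if (!(p$node %in% node_names)) stop("perturbation targets unknown node '", p$node, "'")
  }
  # conflicting overlapping windows on the same node
  if (length(perturbations) > 1L) {
    for (i in seq_along(perturbations)) {
      for (j in seq_len(i - 1L)) {
        a <- perturbations[[i]]; b <- perturbations[[j]]
        if (a$node == b$node && a$mode != b$mode &&
            a$start_step < b$end_step && b$start_step < a$end_step) {
          stop("conflicting clamps on node '", a$node, "' with overlapping windows")
        }
      }
    }
  }
  invisible(TRUE)
}

# ---- influence graph -------------------------------------------------------

#' Signed influence graph of a Boolean network
#'
#' Walks every rule tree and records one signed edge per (regulator, target,
#' sign) combination: sign +1 when the regulator appears under an even number
#' of negations, -1 under an odd number.
#'
#' @param network a [boolean_network()].
#' @return data.frame with columns `from`, `to`, `sign`.
#' @export
influence_graph <- function(network) {
  stopifnot(inherits(network, "boolean_network"))
  edges <- list()
  walk <- function(r, sign, target) {
    switch(r$op,
      const = NULL,
      var = {
        edges[[length(edges) + 1L]] <<- data.frame(from = r$name, to = target,
                                                   sign = sign, stringsAsFactors = FALSE)
        NULL
      },
      not = walk(r$args[[1L]], -sign, target),
      { for (a in r$args) walk(a, sign, target); NULL }
    )
  }
  for (nm in network$node_names) walk(network$rules[[nm]], 1L, nm)
  if (length(edges) == 0L) {
    return(data.frame(from = character(), to = character(), sign = integer()))
  }
  out <- do.call(rbind, edges)
  unique(out)
}

#' Find positive feedback cycles through a given node set
#'
#' Searches the signed influence graph for a cycle whose edge signs multiply
#' to +1 and which visits every node in `through`. Used to verify the two
#' positive feedback loops of the spoCRC network (the IL6/GP130/RAS/AKT/NF-kB
#' cytokine loop and the AKT/beta-catenin/COX2/PGE2/RAS loop).
#'
#' @param network a [boolean_network()].
#' @param through character vector of node names the cycle must contain.
#' @param max_length maximum cycle length considered.
#' @return `TRUE`/`FALSE`.
#' @export
has_positive_cycle_through <- function(network, through, max_length = 20L) {
  ig <- influence_graph(network)
  if (nrow(ig) == 0L) return(FALSE)
  g <- igraph::graph_from_data_frame(ig, directed = TRUE)
  miss <- setdiff(through, igraph::V(g)$name)
  if (length(miss) > 0L) return(FALSE)
  # search simple paths start -> ... -> start through all way-points
  start <- through[[1L]]
  rest <- through[-1L]
  # DFS over simple cycles from start, tracking sign product
  adj <- split(seq_len(nrow(ig)), ig$from)
  found <- FALSE
  visit <- function(node, visited, sign) {
    if (found) return()
    es <- adj[[node]]
    if (is.null(es)) return()
    for (e in es) {
      to <- ig$to[[e]]
      s2 <- sign * ig$sign[[e]]
      if (to == start) {
        if (s2 > 0 && all(rest %in% visited)) { found <<- TRUE; return() }
      } else if (!(to %in% visited) && length(visited) < max_length) {
        visit(to, c(visited, to), s2)
      }
    }
  }
  visit(start, start, 1L)
  found
}
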