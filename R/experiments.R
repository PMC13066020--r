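# Pipeline stages: inflammation studies, mutation panel, target-knockout and
# drug panels, with the staged-initial-condition chains between them.

scenario_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483629)
}

reporting_marginals <- function(result, clusters = spocrc_clusters()) {
  rn <- clusters$reporting_nodes
  out <- vapply(names(rn), function(col) {
    nd <- rn[[col]]
    if (!(nd %in% names(result$end_marginals))) stop("reporting node missing: ", nd)
    unname(result$end_marginals[[nd]])
  }, 0)
  names(out) <- names(rn)
  out
}

phenotype_label <- function(marginals) {
  if (marginals[["proliferation"]] > marginals[["apoptosis"]]) "Proliferative" else "Apoptotic"
}

new_scenario_result <- function(name, result, clusters = spocrc_clusters(),
                                extra = list()) {
  m <- reporting_marginals(result, clusters)
  structure(c(list(name = name, result = result, marginals = m,
                   phenotype = phenotype_label(m)), extra),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario '%s' [%s]\n", x$name, x$phenotype))
  print(round(x$marginals, 3))
  invisible(x)
}

#' Initial conditions for spoCRC scenarios
#'
#' Random runs start every node ON with probability 0.5 except the start-OFF
#' set (the inflammatory cascade including receptors, COX2, PGE2, EP2,
#' apoptosis and proliferation), which starts OFF. Staged runs start each
#' node ON with probability equal to its end-of-run activation frequency in
#' a parent scenario.
#'
#' @param network a [boolean_network()].
#' @param staged_from optional parent `scenario_result`/`ensemble_result`.
#' @return an [initial_condition_spec()].
#' @export
spocrc_initial <- function(network, staged_from = NULL) {
  if (is.null(staged_from)) {
    off <- intersect(spocrc_clusters()$start_off, network$node_names)
    return(initial_condition_spec(stats::setNames(rep(0, length(off)), off), 0.5))
  }
  staged_initial_conditions(staged_from, network)
}

#' Staged initial conditions from a parent run
#'
#' Per-node ON probability equals the parent's window-averaged end marginal;
#' nodes absent from the parent (e.g. freshly attached inhibitor nodes)
#' default to 0.5. Nodes are sampled independently per repetition.
#'
#' @param parent a `scenario_result` or `ensemble_result`.
#' @param network optional network whose node set the returned spec should cover.
#' @return an [initial_condition_spec()].
#' @export
staged_initial_conditions <- function(parent, network = NULL) {
  m <- if (inherits(parent, "scenario_result")) parent$result$end_marginals else parent$end_marginals
  if (!is.null(network)) m <- m[intersect(names(m), network$node_names)]
  initial_condition_spec(m, 0.5)
}

run_stage <- function(name, network, steps, repetitions, seed, perturbations,
                      initial, measurement_window = NULL, extra = list()) {
  cfg <- simulation_config(steps = steps, repetitions = repetitions, seed = seed,
                           initial = initial, perturbations = perturbations,
                           measurement_window = measurement_window)
  res <- run_ensemble(network, cfg)
  new_scenario_result(name, res, extra = extra)
}

clamp_cluster_off <- function(network) {
  lapply(intersect(spocrc_clusters()$inflammatory_cluster, network$node_names),
         perturbation, mode = "FIX_OFF")
}

#' Baseline spoCRC scenarios
#'
#' `run_healthy()` simulates the calibrated healthy model: inflammation
#' cluster present, IL6/CCL2 polymorphisms 0.5, APC clamped ON.
#' `run_no_inflammation()` additionally clamps every inflammatory-cluster
#' node OFF, isolating the epithelial cell from its immune environment.
#'
#' @param steps,repetitions,seed simulation size (published protocol: 1800 steps,
#'   5000 repetitions).
#' @param network the spoCRC network; loaded if not supplied.
#' @return a `scenario_result`.
#' @export
run_healthy <- function(steps = 1800, repetitions = 5000, seed = 1,
                        network = load_spocrc()) {
  run_stage("healthy", network, steps, repetitions, scenario_seed(seed, 1),
            list(perturbation("APC", "FIX_ON")), spocrc_initial(network))
}

#' @rdname run_healthy
#' @export
run_no_inflammation <- function(steps = 1800, repetitions = 5000, seed = 1,
                                network = load_spocrc()) {
  run_stage("no_inflammation", network, steps, repetitions, scenario_seed(seed, 2),
            c(list(perturbation("APC", "FIX_ON")), clamp_cluster_off(network)),
            spocrc_initial(network))
}

#' Sweep the IL6/CCL2 polymorphism strength
#'
#' One scenario per value with the inflammation cluster present and both IL6
#' and CCL2 polymorphisms set to the value. The protocol's tested values are
#' 100%, 85%, 75%, 65%, 50%, 30% and 10%.
#'
#' @param values probabilities in \[0,1\].
#' @inheritParams run_healthy
#' @return named list of `scenario_result`, one per value.
#' @export
run_polymorphism_sweep <- function(values = c(1, 0.85, 0.75, 0.65, 0.5, 0.3, 0.1),
                                   steps = 1800, repetitions = 5000, seed = 1,
                                   network = load_spocrc()) {
  stopifnot(all(values >= 0 & values <= 1))
  out <- list()
  for (k in seq_along(values)) {
    v <- values[[k]]
    net <- set_polymorphisms(network, c(IL6 = v, CCL2 = v))
    out[[sprintf("poly_%g", v)]] <-
      run_stage(sprintf("inflammation_poly_%g", v), net, steps, repetitions,
                scenario_seed(seed, 10 + k),
                list(perturbation("APC", "FIX_ON")), spocrc_initial(net))
  }
  out
}

#' Chronic and transient inflammation protocols
#'
#' Staged from a healthy run: after 200 steps the dendritic-cell node is
#' clamped ON for 100 steps (`TRANSIENT_100`), 300 steps (`TRANSIENT_300`)
#' or the remainder of the run (`CHRONIC`). For transient modes the recovery
#' phase is simulated as a separate staged run initialized from the
#' post-inflammation marginals, and stage outputs are concatenated.
#'
#' @param mode inflammation protocol.
#' @param healthy optional pre-computed healthy `scenario_result` (computed
#'   at the protocol sizes when missing).
#' @param post_steps length of the chronic phase / recovery phase.
#' @inheritParams run_healthy
#' @return a `scenario_result`; extra fields `apoptosis_pre` (mean apoptosis
#'   frequency over the 50 steps before the clamp) and `apoptosis_post` (end
#'   marginal of the final stage).
#' @export
run_inflammation_protocol <- function(mode = c("CHRONIC", "TRANSIENT_100", "TRANSIENT_300"),
                                      steps = 1800, repetitions = 5000, seed = 1,
                                      network = load_spocrc(), healthy = NULL,
                                      post_steps = 500) {
  mode <- match.arg(mode)
  if (is.null(healthy)) healthy <- run_healthy(steps, repetitions, seed, network)
  duration <- switch(mode, CHRONIC = Inf, TRANSIENT_100 = 100, TRANSIENT_300 = 300)
  onset <- 200
  stage_steps <- if (is.finite(duration)) onset + duration else onset + post_steps
  clamp <- perturbation("DC", "FIX_ON", start_step = onset,
                        end_step = if (is.finite(duration)) onset + duration else Inf)
  stage1 <- run_stage(paste0("inflammation_", mode), network, stage_steps,
                      repetitions, scenario_seed(seed, 20),
                      list(perturbation("APC", "FIX_ON"), clamp),
                      spocrc_initial(network, staged_from = healthy))
  apo <- stage1$result$frequency["Apoptosis", ]
  pre <- mean(apo[as.character((onset - 50):(onset - 1))])
  if (!is.finite(duration)) {
    stage1$apoptosis_pre <- pre
    stage1$apoptosis_post <- unname(stage1$result$end_marginals[["Apoptosis"]])
    return(stage1)
  }
  recovery <- run_stage(paste0("recovery_", mode), network, post_steps, repetitions,
                        scenario_seed(seed, 21),
                        list(perturbation("APC", "FIX_ON")),
                        spocrc_initial(network, staged_from = stage1))
  combined <- stage1
  combined$result$frequency <- cbind(stage1$result$frequency,
                                     recovery$result$frequency[, -1L, drop = FALSE])
  colnames(combined$result$frequency) <- as.character(seq_len(ncol(combined$result$frequency)) - 1L)
  combined$result$end_marginals <- recovery$result$end_marginals
  combined$marginals <- reporting_marginals(recovery$result)
  combined$phenotype <- phenotype_label(combined$marginals)
  combined$apoptosis_pre <- pre
  combined$apoptosis_post <- unname(recovery$result$end_marginals[["Apoptosis"]])
  combined
}

spocrc_default_panel <- function() {
  list(healthy = character(),
       LOSS_18Q = "LOSS_18Q",
       APC_LOF = "APC_LOF",
       RAS_GOF = "RAS_GOF",
       P53_LOF = "P53_LOF",
       "APC_LOF+P53_LOF" = c("APC_LOF", "P53_LOF"),
       "APC_LOF+RAS_GOF" = c("APC_LOF", "RAS_GOF"),
       "APC_LOF+RAS_GOF+LOSS_18Q" = c("APC_LOF", "RAS_GOF", "LOSS_18Q"),
       ALL = c("APC_LOF", "RAS_GOF", "P53_LOF", "LOSS_18Q"))
}

# staging parents per the published protocol: single mutations stage from
# the healthy run; APC+P53 and APC+RAS from the APC run; APC+RAS+18q from
# APC+RAS; the all-mutation scenario from APC+RAS+18q.
panel_parent <- function(name) {
  switch(name,
    "healthy" = NULL,
    "LOSS_18Q" = "healthy", "APC_LOF" = "healthy",
    "RAS_GOF" = "healthy", "P53_LOF" = "healthy",
    "APC_LOF+P53_LOF" = "APC_LOF",
    "APC_LOF+RAS_GOF" = "APC_LOF",
    "APC_LOF+RAS_GOF+LOSS_18Q" = "APC_LOF+RAS_GOF",
    "ALL" = "APC_LOF+RAS_GOF+LOSS_18Q",
    "healthy")
}

#' Run the CRC mutation panel
#'
#' Simulates every mutation set with the staging chain of the published
#' protocol (see [staged_initial_conditions()]): each scenario's initial
#' conditions are drawn from the end marginals of its parent scenario.
#' Mutation clamps span the whole run.
#'
#' @param panel named list mapping scenario name to a character vector of
#'   mutation names (see [mutation_set()]); defaults to the full panel
#'   including the healthy reference.
#' @inheritParams run_healthy
#' @return named list of `scenario_result` (one per panel row), each with a
#'   `mutations` field; attribute `summary` holds the reporting table from
#'   [summarize_panel()].
#' @export
run_mutation_panel <- function(panel = spocrc_default_panel(),
                               steps = 1800, repetitions = 5000, seed = 1,
                               network = load_spocrc()) {
  out <- list()
  for (k in seq_along(panel)) {
    name <- names(panel)[[k]]
    parent_name <- panel_parent(name)
    parent <- if (is.null(parent_name)) NULL else out[[parent_name]]
    if (!is.null(parent_name) && is.null(parent))
      stop("staging chain broken: '", name, "' needs parent '", parent_name, "'")
    ms <- mutation_set(panel[[k]])
    perts <- ms$clamps
    if (!("APC_LOF" %in% panel[[k]])) perts <- c(perts, list(perturbation("APC", "FIX_ON")))
    init <- if (is.null(parent)) spocrc_initial(network)
            else spocrc_initial(network, staged_from = parent)
    out[[name]] <- run_stage(name, network, steps, repetitions,
                             scenario_seed(seed, 30 + k), perts, init,
                             extra = list(mutations = ms, initial = init,
                                          stage_seed = scenario_seed(seed, 30 + k)))
  }
  attr(out, "summary") <- summarize_panel(out)
  out
}

#' Single-target knockout panel
#'
#' For every target and every mutation background, reruns the mutant
#' scenario with the target clamped OFF for the whole run (total inhibition)
#' and computes [effect_scores()] against the untreated mutant and the
#' healthy reference. Treated runs reuse the untreated scenario's staged
#' initial conditions and seed so the clamp is the only difference.
#'
#' @param targets character vector of knockout targets.
#' @param mutation_panel result of [run_mutation_panel()] (must contain a
#'   `healthy` row).
#' @inheritParams run_healthy
#' @return data.frame with one row per (target, mutation background).
#' @export
run_inhibition_panel <- function(targets = c("COX2", "PDE5", "AKT", "NFkB", "FZD", "BCL2"),
                                 mutation_panel, network = load_spocrc()) {
  stopifnot("healthy" %in% names(mutation_panel))
  unknown <- setdiff(targets, network$node_names)
  if (length(unknown) > 0L) stop("unknown knockout target(s): ", paste(unknown, collapse = ", "))
  healthy <- mutation_panel[["healthy"]]
  rows <- list()
  for (tg in targets) {
    for (name in setdiff(names(mutation_panel), "healthy")) {
      un <- mutation_panel[[name]]
      cfg <- un$result$config
      apc_free <- !any(vapply(un$mutations$clamps, function(p) p$node == "APC", TRUE))
      treated <- run_stage(sprintf("%s_ko_%s", name, tg), network,
                           cfg$steps, cfg$repetitions, un$stage_seed,
                           c(un$mutations$clamps,
                             if (apc_free) list(perturbation("APC", "FIX_ON")),
                             list(perturbation(tg, "FIX_OFF"))),
                           un$initial)
      es <- effect_scores(treated, un, healthy)
      rows[[length(rows) + 1L]] <-
        data.frame(target = tg, mutations = name,
                   apoptosis_restoration = es$apoptosis_restoration,
                   proliferation_inhibition = es$proliferation_inhibition,
                   treated_apoptosis = treated$marginals[["apoptosis"]],
                   treated_proliferation = treated$marginals[["proliferation"]],
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Multi-target drug panel (celecoxib / sulindac profiles)
#'
#' Attaches the profile's inhibitor nodes to the network
#' ([attach_inhibitors()]) and reruns every mutant scenario on the extended
#' network; effect scores are computed against the untreated mutant and
#' healthy runs of `mutation_panel`.
#'
#' @param profiles character vector of profile names.
#' @inheritParams run_inhibition_panel
#' @return data.frame with one row per (drug, mutation background).
#' @export
run_drug_panel <- function(profiles = c("celecoxib", "sulindac"),
                           mutation_panel, network = load_spocrc()) {
  stopifnot("healthy" %in% names(mutation_panel))
  healthy <- mutation_panel[["healthy"]]
  rows <- list()
  for (pf in profiles) {
    prof <- drug_profile(pf)
    net2 <- attach_inhibitors(network, prof)
    for (name in setdiff(names(mutation_panel), "healthy")) {
      un <- mutation_panel[[name]]
      cfg <- un$result$config
      # stage treated runs from the same parent marginals the untreated run
      # used; the fresh inhibitor nodes default to 0.5
      init <- initial_condition_spec(un$initial$probabilities, 0.5)
      apc_free <- !any(vapply(un$mutations$clamps, function(p) p$node == "APC", TRUE))
      treated <- run_stage(sprintf("%s_%s", name, pf), net2,
                           cfg$steps, cfg$repetitions, un$stage_seed,
                           c(un$mutations$clamps,
                             if (apc_free) list(perturbation("APC", "FIX_ON"))),
                           init)
      es <- effect_scores(treated, un, healthy)
      rows[[length(rows) + 1L]] <-
        data.frame(drug = pf, mutations = name,
                   apoptosis_restoration = es$apoptosis_restoration,
                   proliferation_inhibition = es$proliferation_inhibition,
                   treated_apoptosis = treated$marginals[["apoptosis"]],
                   treated_proliferation = treated$marginals[["proliferation"]],
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Summary table of scenario results
#'
#' @param results list of `scenario_result` objects.
#' @return data.frame with columns scenario, apoptosis, proliferation,
#'   b_catenin, cox2_pge2, akt, nfkb, il6, phenotype.
#' @export
summarize_panel <- function(results) {
  if (length(results) == 0L) stop("no scenario results to summarize")
  rows <- lapply(results, function(r) {
    data.frame(scenario = r$name, as.list(round(r$marginals, 4)),
               phenotype = r$phenotype, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
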