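# The spoCRC model: loader for the packaged 87-node rule set, structural
# validation against the interactions documented for the model, mutation
# sets, and COXIB inhibitor-node attachment.

spocrc_extdata <- function(file) {
  path <- system.file("extdata", file, package = "spocrc")
  if (path == "") stop("packaged data file missing: ", file)
  path
}

# every interaction anchored in the model's description: one signed edge each
spocrc_anchors <- function() {
  e <- function(from, to, sign) data.frame(from = from, to = to, sign = sign,
                                           stringsAsFactors = FALSE)
  rbind(
    e("survivin", "SMAC", -1L), e("survivin", "CASP3", -1L),
    e("survivin", "CASP9", -1L), e("survivin", "CYTc", -1L),
    e("survivin", "Proliferation", 1L),
    e("NFkB", "survivin", 1L), e("STAT", "survivin", 1L),
    e("bcatenin", "survivin", 1L), e("MDM2", "survivin", 1L),
    e("p53", "survivin", -1L), e("SMAD", "survivin", -1L),
    e("PDE5", "cGMP", -1L), e("cGMP", "PKG", 1L), e("PKG", "FOXO4", 1L),
    e("FOXO4", "bcatenin", -1L),
    e("WNT", "FZD", 1L), e("FZD", "Axin", -1L),
    e("Netrin", "DCC", -1L), e("DCC", "CASP9", 1L), e("diDCC", "PI3K", 1L),
    e("BH3", "BCL2", -1L), e("Stress", "BH3", 1L),
    e("PI3K", "PDK1", 1L), e("PDK1", "AKT", 1L),
    e("CASP3", "AKT", -1L), e("PP2A", "AKT", -1L),
    e("MEKK1", "SEK1", 1L), e("SEK1", "JNK1", 1L),
    e("bcatenin", "TCFLEF", 1L), e("TCFLEF", "bcatenin", 1L),
    e("TCFLEF", "COX2", 1L), e("TCFLEF", "survivin", 1L),
    e("TCFLEF", "CyclinD1", 1L)
  )
}

#' Validate the structure of a loaded spoCRC network
#'
#' Checks that every documented interaction of the model is present in the
#' signed influence graph with the stated sign (and not with the opposite
#' sign), and that both positive feedback loops exist: the cytokine loop
#' through IL6, GP130, RAS, AKT and NF-kB, and the
#' AKT/beta-catenin/COX2/PGE2/RAS loop.
#'
#' @param network a [boolean_network()].
#' @return `TRUE` invisibly; otherwise an error naming every violated anchor.
#' @export
validate_spocrc_structure <- function(network) {
  ig <- influence_graph(network)
  key <- paste(ig$from, ig$to, ig$sign)
  anchors <- spocrc_anchors()
  bad <- character()
  for (k in seq_len(nrow(anchors))) {
    a <- anchors[k, ]
    want <- paste(a$from, a$to, a$sign)
    clash <- paste(a$from, a$to, -a$sign)
    lab <- sprintf("%s %s %s", a$from, if (a$sign > 0) "->" else "-|", a$to)
    if (!(want %in% key)) bad <- c(bad, paste("missing:", lab))
    else if (clash %in% key) bad <- c(bad, paste("ambiguous sign:", lab))
  }
  if (!has_positive_cycle_through(network, c("IL6", "GP130", "RAS", "AKT", "NFkB")))
    bad <- c(bad, "missing positive feedback loop: IL6/GP130/RAS/AKT/NFkB")
  if (!has_positive_cycle_through(network, c("AKT", "bcatenin", "COX2", "PGE2", "RAS")))
    bad <- c(bad, "missing positive feedback loop: AKT/bcatenin/COX2/PGE2/RAS")
  if (length(bad) > 0L)
    stop("spoCRC structural validation failed:\n  ", paste(bad, collapse = "\n  "))
  invisible(TRUE)
}

#' Load the packaged spoCRC network
#'
#' Parses the packaged 87-node rule file (a reconstruction of the published
#' model; see the rule file's header comments), applies the calibrated
#' default polymorphisms (WNT 0.1, Netrin 0.5, CAD 0.1, PDE5 0.9,
#' Stress 0.02, IL6 0.5, CCL2 0.5) and runs structural validation.
#'
#' @param validate run [validate_spocrc_structure()] (default TRUE).
#' @return a [boolean_network()] with 87 nodes.
#' @export
load_spocrc <- function(validate = TRUE) {
  path <- spocrc_extdata("spocrc_reconstruction.bnet")
  net <- parse_rule_file(path, is_path = TRUE)
  net$metadata <- list(name = "spoCRC",
                       provenance = "synthetic reconstruction",
                       rule_file = path,
                       checksum = unname(tools::md5sum(path)))
  if (validate) validate_spocrc_structure(net)
  net
}

#' Node-set rosters of the spoCRC model
#'
#' `spocrc_clusters()` returns the inflammatory-cluster roster (immune
#' cells, cytokines, chemokines and their receptors; clamped OFF to remove
#' inflammation), the start-OFF set (nodes always initialized OFF), and the
#' reporting-node map used in summary tables.
#'
#' @return a list with elements `inflammatory_cluster`, `start_off`,
#'   `reporting_nodes`.
#' @export
spocrc_clusters <- function() {
  yaml::read_yaml(spocrc_extdata("spocrc_clusters.yaml"))
}

#' CRC mutation sets as clamp collections
#'
#' Builds a mutation set from the named panel: `APC_LOF` (APC clamped OFF),
#' `P53_LOF` (p53 OFF), `RAS_GOF` (RAS ON), `LOSS_18Q` (SMAD, DCC and diDCC
#' OFF). Several names yield the union of clamps.
#'
#' @param names character vector of mutation names (possibly empty for the
#'   identity set).
#' @return object of class `mutation_set` with fields `name` and `clamps`
#'   (list of [perturbation()]).
#' @export
mutation_set <- function(names = character()) {
  defs <- yaml::read_yaml(spocrc_extdata("mutations.yaml"))
  unknown <- setdiff(names, names(defs))
  if (length(unknown) > 0L) stop("unknown mutation set(s): ", paste(unknown, collapse = ", "))
  clamps <- list()
  for (nm in names) {
    for (node in names(defs[[nm]])) {
      mode <- if (identical(defs[[nm]][[node]], "on")) "FIX_ON" else "FIX_OFF"
      clamps[[length(clamps) + 1L]] <- perturbation(node, mode)
    }
  }
  structure(list(name = if (length(names) == 0L) "none" else paste(names, collapse = "+"),
                 clamps = clamps),
            class = "mutation_set")
}

#' Add a mutation set's clamps to a simulation configuration
#'
#' The returned configuration's perturbation set is the union of the existing
#' perturbations and the mutation clamps (whole-run). Conflicting clamps on
#' the same node raise an error.
#'
#' @param config a [simulation_config()].
#' @param mutations a [mutation_set()].
#' @param network optional [boolean_network()] to validate node names against.
#' @return the augmented configuration.
#' @export
apply_mutation_set <- function(config, mutations, network = NULL) {
  stopifnot(inherits(config, "simulation_config"), inherits(mutations, "mutation_set"))
  config$perturbations <- c(config$perturbations, mutations$clamps)
  if (!is.null(network)) {
    validate_perturbations(config$perturbations, network$node_names)
  } else {
    validate_perturbations(config$perturbations,
                           unique(vapply(config$perturbations, function(p) p$node, "")))
  }
  config
}

#' COXIB inhibition profiles
#'
#' `drug_profile("celecoxib")` and `drug_profile("sulindac")` return the
#' packaged target-potency maps (both block COX2 at 0.9; celecoxib inhibits
#' AKT, NF-kB and PDE5 at 0.3; sulindac cannot inhibit AKT). A custom profile
#' is built by passing `targets` directly.
#'
#' @param name `"celecoxib"`, `"sulindac"`, or `"custom"`.
#' @param targets named numeric vector (target node -> inhibitor
#'   polymorphism) for custom profiles.
#' @return object of class `drug_profile`.
#' @export
drug_profile <- function(name = c("celecoxib", "sulindac", "custom"), targets = NULL) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(targets)) targets <- numeric()
  } else {
    defs <- yaml::read_yaml(spocrc_extdata("drugs.yaml"))
    targets <- unlist(defs[[name]])
  }
  if (length(targets) > 0L && any(targets < 0 | targets > 1))
    stop("inhibitor polymorphisms must lie in [0,1]")
  structure(list(name = name, targets = targets), class = "drug_profile")
}

#' Attach COXIB inhibitor nodes to a network
#'
#' For every target `T` with potency `p` in the profile, adds a node
#' `COXIB_T` with constant-TRUE rule and polymorphism `p`, and rewrites the
#' target's rule to `(original rule) & !COXIB_T`: whenever the drug node is
#' active it shuts its target down. Applying a profile twice raises an error
#' rather than double-wrapping rules.
#'
#' @param network a [boolean_network()].
#' @param profile a [drug_profile()].
#' @return the extended network (node count grows by the number of targets).
#' @export
attach_inhibitors <- function(network, profile) {
  stopifnot(inherits(network, "boolean_network"), inherits(profile, "drug_profile"))
  if (length(profile$targets) == 0L) return(network)
  targets <- names(profile$targets)
  unknown <- setdiff(targets, network$node_names)
  if (length(unknown) > 0L) stop("unknown inhibitor target(s): ", paste(unknown, collapse = ", "))
  inhib <- paste0("COXIB_", targets)
  dup <- intersect(inhib, network$node_names)
  if (length(dup) > 0L)
    stop("inhibitor node(s) already present (profile applied twice?): ",
         paste(dup, collapse = ", "))
  rules <- network$rules
  poly <- network$polymorphisms
  for (k in seq_along(targets)) {
    tg <- targets[[k]]
    rules[[tg]] <- rule_and(rules[[tg]], rule_not(rule_var(inhib[[k]])))
    rules[[inhib[[k]]]] <- rule_const(TRUE)
    poly[[inhib[[k]]]] <- unname(profile$targets[[k]])
  }
  out <- boolean_network(rules, poly, metadata = network$metadata)
  out$metadata$drug <- profile$name
  out
}
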