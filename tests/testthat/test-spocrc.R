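test_that("the packaged network loads with 87 nodes and passes structural validation", {
  net <- load_spocrc()
  expect_s3_class(net, "boolean_network")
  expect_length(net$node_names, 87)
  expect_true(validate_spocrc_structure(net))
  expect_identical(net$metadata$provenance, "synthetic reconstruction")
})

test_that("the loaded AKT rule matches the documented form", {
  net <- load_spocrc()
  expect_identical(format_rule(net$rules[["AKT"]]), "PDK1 & !(CASP3 | PP2A)")
})

test_that("the calibrated default polymorphisms are exactly the documented seven", {
  net <- load_spocrc()
  pl <- net$polymorphisms[net$polymorphisms < 1]
  expect_mapequal(pl, c(WNT = 0.1, Netrin = 0.5, CAD = 0.1, PDE5 = 0.9,
                        Stress = 0.02, IL6 = 0.5, CCL2 = 0.5))
})

test_that("the influence graph holds the netrin inhibition and both feedback loops", {
  net <- load_spocrc()
  ig <- influence_graph(net)
  expect_true(any(ig$from == "Netrin" & ig$to == "DCC" & ig$sign == -1L))
  expect_true(has_positive_cycle_through(net, c("IL6", "GP130", "RAS", "AKT", "NFkB")))
  expect_true(has_positive_cycle_through(net, c("AKT", "bcatenin", "COX2", "PGE2", "RAS")))
})

test_that("structural validation reports violated anchors by name", {
  net <- load_spocrc()
  broken <- net
  broken$rules[["cGMP"]] <- rule_const(FALSE) # drop PDE5 -| cGMP
  expect_error(validate_spocrc_structure(broken), "PDE5 -\\| cGMP")
})

test_that("cluster rosters cover the documented start-OFF nodes", {
  cl <- spocrc_clusters()
  expect_true(all(c("COX2", "PGE2", "EP2", "Apoptosis", "Proliferation") %in% cl$start_off))
  expect_true(all(cl$inflammatory_cluster %in% cl$start_off))
  expect_true(all(c("DC", "MAC", "TREG", "TH", "IL6", "CCL2", "GP130") %in%
                    cl$inflammatory_cluster))
  net <- load_spocrc()
  expect_true(all(cl$start_off %in% net$node_names))
})

test_that("mutation sets encode the documented clamps and union correctly", {
  one <- mutation_set("APC_LOF")
  expect_length(one$clamps, 1)
  expect_identical(one$clamps[[1]]$node, "APC")
  expect_identical(one$clamps[[1]]$mode, "FIX_OFF")
  ras <- mutation_set("RAS_GOF")
  expect_identical(ras$clamps[[1]]$mode, "FIX_ON")
  loss <- mutation_set("LOSS_18Q")
  expect_setequal(vapply(loss$clamps, `[[`, "", "node"), c("SMAD", "DCC", "diDCC"))
  all4 <- mutation_set(c("APC_LOF", "RAS_GOF", "P53_LOF", "LOSS_18Q"))
  expect_length(all4$clamps, 6)
  expect_error(mutation_set("TP53"), "unknown mutation set")
})

test_that("apply_mutation_set unions clamps and flags conflicts", {
  net <- load_spocrc()
  cfg <- simulation_config(steps = 10, repetitions = 2, seed = 1)
  same <- apply_mutation_set(cfg, mutation_set(character()), net)
  expect_identical(same$perturbations, cfg$perturbations)
  cfg2 <- apply_mutation_set(cfg, mutation_set("APC_LOF"), net)
  expect_length(cfg2$perturbations, 1)
  cfg3 <- simulation_config(steps = 10, repetitions = 2, seed = 1,
                            perturbations = list(perturbation("APC", "FIX_ON")))
  expect_error(apply_mutation_set(cfg3, mutation_set("APC_LOF"), net), "conflicting")
})

test_that("drug profiles carry the documented potencies", {
  cele <- drug_profile("celecoxib")
  expect_mapequal(cele$targets, c(COX2 = 0.9, AKT = 0.3, NFkB = 0.3, PDE5 = 0.3))
  suli <- drug_profile("sulindac")
  expect_mapequal(suli$targets, c(COX2 = 0.9, AKT = 0.0, NFkB = 0.3, PDE5 = 0.3))
})

test_that("attach_inhibitors wraps targets and refuses double application", {
  net <- load_spocrc()
  cele <- drug_profile("celecoxib")
  net2 <- attach_inhibitors(net, cele)
  expect_length(net2$node_names, 91)
  expect_true(all(paste0("COXIB_", names(cele$targets)) %in% net2$node_names))
  expect_equal(unname(net2$polymorphisms[paste0("COXIB_", names(cele$targets))]),
               unname(cele$targets))
  # wrapped rule: (original) & !COXIB_T
  akt2 <- net2$rules[["AKT"]]
  expect_identical(format_rule(akt2),
                   "PDK1 & !(CASP3 | PP2A) & !COXIB_AKT")
  expect_error(attach_inhibitors(net2, cele), "already present")
  expect_identical(attach_inhibitors(net, drug_profile("custom")), net)
  expect_error(attach_inhibitors(net, drug_profile("custom", c(NOPE = 0.5))),
               "unknown inhibitor target")
})

test_that("a zero-potency inhibitor node never fires", {
  net <- attach_inhibitors(load_spocrc(), drug_profile("sulindac"))
  cfg <- simulation_config(steps = 30, repetitions = 200, seed = 2,
                           initial = spocrc_initial(net))
  res <- run_ensemble(net, cfg)
  expect_equal(unname(res$end_marginals[["COXIB_AKT"]]), 0)
  expect_gt(res$end_marginals[["COXIB_COX2"]], 0.8)
})
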