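# Pipeline-stage behavior at reduced problem sizes (full-size protocol runs
# live in the acceptance suite).

test_that("random initial conditions force the start-OFF roster to zero at step 0", {
  net <- load_spocrc()
  cfg <- simulation_config(steps = 2, repetitions = 300, seed = 5,
                           initial = spocrc_initial(net))
  f0 <- run_ensemble(net, cfg)$frequency[, "0"]
  off <- spocrc_clusters()$start_off
  expect_true(all(f0[off] == 0))
  others <- setdiff(names(f0), off)
  expect_true(all(abs(f0[others] - 0.5) < mc_tol(0.5, 300)))
})

test_that("staged initial conditions reproduce parent end marginals", {
  net <- load_spocrc()
  parent <- run_healthy(steps = 120, repetitions = 300, seed = 2, network = net)
  init <- staged_initial_conditions(parent, net)
  m <- parent$result$end_marginals
  expect_equal(init$probabilities[names(m)], m)
  # degenerate parents initialize deterministically; 0.5 parents hit 0.5 +- 3 SE
  cfg <- simulation_config(steps = 1, repetitions = 400, seed = 9, initial = init)
  f0 <- run_ensemble(net, cfg)$frequency[, "0"]
  hard <- names(m)[m %in% c(0, 1)]
  expect_equal(f0[hard], m[hard])
  mid <- names(m)[abs(m - 0.5) < 0.1]
  expect_true(all(abs(f0[mid] - m[mid]) < mc_tol(0.5, 400)))
})

test_that("scenario staging chain is enforced", {
  expect_error(run_mutation_panel(panel = list(ALL = c("APC_LOF", "RAS_GOF", "P53_LOF", "LOSS_18Q")),
                                  steps = 10, repetitions = 2, seed = 1,
                                  network = load_spocrc()),
               "staging chain broken")
})

test_that("mutation clamps hold exactly through panel scenarios", {
  net <- load_spocrc()
  pan <- run_mutation_panel(panel = list(healthy = character(), RAS_GOF = "RAS_GOF"),
                            steps = 60, repetitions = 50, seed = 3, network = net)
  f <- pan$RAS_GOF$result$frequency
  expect_true(all(f["RAS", -1L] == 1))
  expect_s3_class(attr(pan, "summary"), "data.frame")
  expect_equal(attr(pan, "summary")$scenario, c("healthy", "RAS_GOF"))
})

test_that("the DC clamp window is exact in transient protocols", {
  net <- load_spocrc()
  h <- run_healthy(steps = 150, repetitions = 40, seed = 4, network = net)
  r <- run_inflammation_protocol("TRANSIENT_100", steps = 150, repetitions = 40,
                                 seed = 4, network = net, healthy = h,
                                 post_steps = 60)
  dc <- r$result$frequency["DC", ]
  expect_true(all(dc[as.character(200:299)] == 1))
  expect_true(all(dc[as.character(310:360)] < 1))
  expect_true(is.finite(r$apoptosis_pre) && is.finite(r$apoptosis_post))
})

test_that("a null drug profile reproduces the untreated run exactly", {
  net <- load_spocrc()
  pan <- run_mutation_panel(panel = list(healthy = character(), APC_LOF = "APC_LOF"),
                            steps = 80, repetitions = 60, seed = 6, network = net)
  eff <- run_drug_panel(profiles = "custom", mutation_panel = pan, network = net)
  expect_equal(eff$apoptosis_restoration, 0)
  expect_equal(eff$proliferation_inhibition, 0)
})

test_that("a clamped knockout target has zero marginal in the treated run", {
  net <- load_spocrc()
  pan <- run_mutation_panel(panel = list(healthy = character(), APC_LOF = "APC_LOF"),
                            steps = 80, repetitions = 60, seed = 7, network = net)
  eff <- run_inhibition_panel(targets = "COX2", mutation_panel = pan, network = net)
  expect_equal(nrow(eff), 1)
  expect_true(is.finite(eff$apoptosis_restoration))
  # rerun the treated scenario to confirm the clamp contract
  un <- pan$APC_LOF
  treated <- run_ensemble(net, simulation_config(
    steps = 80, repetitions = 60, seed = un$stage_seed, initial = un$initial,
    perturbations = c(un$mutations$clamps, list(perturbation("COX2", "FIX_OFF")))))
  expect_equal(unname(treated$end_marginals[["COX2"]]), 0)
})

test_that("phenotype labels follow the dominant readout", {
  fake <- function(a, p) {
    structure(list(name = "x", marginals = c(apoptosis = a, proliferation = p)),
              class = "scenario_result")
  }
  res <- run_healthy(steps = 30, repetitions = 20, seed = 1, network = load_spocrc())
  expect_true(res$phenotype %in% c("Apoptotic", "Proliferative"))
  expect_identical(res$phenotype,
                   if (res$marginals[["proliferation"]] > res$marginals[["apoptosis"]])
                     "Proliferative" else "Apoptotic")
})

test_that("rebuilding a staged scenario from the same parent and seed is deterministic", {
  net <- load_spocrc()
  h <- run_healthy(steps = 100, repetitions = 50, seed = 8, network = net)
  mk <- function() {
    cfg <- simulation_config(steps = 100, repetitions = 50, seed = 99,
                             initial = staged_initial_conditions(h, net),
                             perturbations = mutation_set("P53_LOF")$clamps)
    run_ensemble(net, cfg)$frequency
  }
  expect_identical(mk(), mk())
})
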