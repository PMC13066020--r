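test_that("node updates honor polymorphism limits", {
  rule <- rule_const(TRUE)
  set.seed(1)
  expect_true(update_node(rule, logical(), polymorphism = 1))
  expect_false(update_node(rule, logical(), polymorphism = 0))
  expect_false(update_node(rule_const(FALSE), logical(), polymorphism = 1))
})

test_that("a satisfied rule activates with its polymorphism probability", {
  net <- const_net(0.5)
  cfg <- simulation_config(steps = 20, repetitions = 10000, seed = 11,
                           initial = initial_condition_spec(c(A = 0)),
                           measurement_window = 1)
  res <- run_ensemble(net, cfg)
  draws <- res$frequency["A", -1L]
  expect_true(all(abs(draws - 0.5) < mc_tol(0.5, 10000)))
})

test_that("constant networks reach their literals in one step", {
  net <- boolean_network(list(A = rule_const(TRUE), B = rule_const(FALSE)))
  cfg <- simulation_config(steps = 5, repetitions = 1,
                           initial = initial_condition_spec(c(A = 0, B = 1)),
                           seed = 4, measurement_window = 1)
  res <- run_ensemble(net, cfg)
  expect_equal(unname(res$frequency["A", ]), c(0, 1, 1, 1, 1, 1))
  expect_equal(unname(res$frequency["B", ]), c(1, 0, 0, 0, 0, 0))
})

test_that("the negation oscillator toggles every step", {
  cfg <- simulation_config(steps = 6, repetitions = 1, seed = 2,
                           initial = initial_condition_spec(c(A = 0)),
                           measurement_window = 1)
  res <- run_ensemble(oscillator_net(), cfg)
  expect_equal(unname(res$frequency["A", ]), c(0, 1, 0, 1, 0, 1, 0))
})

test_that("ensembles are reproducible bit-for-bit from the seed", {
  net <- generate_toy_network(5, 0.5, c(0.4, 1), seed = 9)
  cfg <- simulation_config(steps = 40, repetitions = 200, seed = 123)
  r1 <- run_ensemble(net, cfg)
  r2 <- run_ensemble(net, cfg)
  expect_identical(r1$frequency, r2$frequency)
  r3 <- run_ensemble(net, simulation_config(steps = 40, repetitions = 200, seed = 124))
  expect_false(identical(r1$frequency, r3$frequency))
})

test_that("frequencies stay in [0,1] and clamps are exact", {
  net <- generate_toy_network(6, 0.5, c(0.3, 1), seed = 5)
  cfg <- simulation_config(steps = 50, repetitions = 300, seed = 7,
                           perturbations = list(
                             perturbation("N1", "FIX_ON", start_step = 10, end_step = 30),
                             perturbation("N2", "FIX_OFF")))
  res <- run_ensemble(net, cfg)
  expect_true(all(res$frequency >= 0 & res$frequency <= 1))
  expect_true(all(res$frequency["N1", as.character(10:29)] == 1))
  expect_true(all(res$frequency["N2", as.character(1:50)] == 0))
  expect_equal(unname(res$end_marginals[["N2"]]), 0)
})

test_that("a whole-run FIX_ON clamp pins the end marginal at one", {
  net <- generate_toy_network(4, 0.5, c(0.3, 1), seed = 6)
  cfg <- simulation_config(steps = 30, repetitions = 100, seed = 8,
                           perturbations = list(perturbation("N3", "FIX_ON")))
  expect_equal(unname(run_ensemble(net, cfg)$end_marginals[["N3"]]), 1)
})

test_that("conflicting overlapping clamps are rejected", {
  net <- const_net()
  expect_error(
    run_ensemble(net, simulation_config(steps = 10, repetitions = 1, seed = 1,
                                        perturbations = list(perturbation("A", "FIX_ON"),
                                                             perturbation("A", "FIX_OFF")))),
    "conflicting clamps")
  # non-overlapping windows with different modes are fine
  cfg <- simulation_config(steps = 10, repetitions = 5, seed = 1,
                           perturbations = list(
                             perturbation("A", "FIX_ON", 1, 5),
                             perturbation("A", "FIX_OFF", 5, 11)),
                           measurement_window = 1)
  expect_equal(unname(run_ensemble(net, cfg)$end_marginals[["A"]]), 0)
})

test_that("activation frequency is non-decreasing in a node's polymorphism", {
  levels <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  marg <- vapply(levels, function(p) {
    cfg <- simulation_config(steps = 60, repetitions = 2000, seed = 21)
    run_ensemble(relay_net(p), cfg)$end_marginals[["A"]]
  }, 0)
  expect_true(all(diff(marg) > 0))
})

test_that("declaration order does not change expected marginals", {
  rules <- list(A = rule_const(TRUE), B = rule_var("A"), C = rule_or(rule_var("A"), rule_var("B")))
  net1 <- boolean_network(rules, c(A = 0.6))
  net2 <- boolean_network(rules[c("C", "A", "B")], c(A = 0.6))
  cfg1 <- simulation_config(steps = 50, repetitions = 4000, seed = 31)
  cfg2 <- simulation_config(steps = 50, repetitions = 4000, seed = 32)
  m1 <- run_ensemble(net1, cfg1)$end_marginals
  m2 <- run_ensemble(net2, cfg2)$end_marginals[names(rules)]
  expect_true(all(abs(m1 - m2) < mc_tol(0.6, 4000) * 2))
})

test_that("the single-node update scheme is slower but converges to the same place", {
  net <- relay_net(1)
  fast <- simulation_config(steps = 30, repetitions = 500, seed = 3)
  slow <- simulation_config(steps = 30, repetitions = 500, seed = 3, update_scheme = "single")
  mf <- run_ensemble(net, fast)$frequency["B", "3"]
  ms <- run_ensemble(net, slow)$frequency["B", "3"]
  expect_gt(mf, ms) # permutation scheme relays faster
  long <- simulation_config(steps = 400, repetitions = 500, seed = 3,
                            update_scheme = "single", measurement_window = 10)
  expect_gt(run_ensemble(net, long)$end_marginals[["B"]], 0.95)
})

test_that("snapshot (non-evolving) evaluation behaves synchronously", {
  # two-node swap network: A = B, B = A; from (1,0) synchronous update swaps forever
  net <- boolean_network(list(A = rule_var("B"), B = rule_var("A")))
  cfg <- simulation_config(steps = 4, repetitions = 1, seed = 5, evolving = FALSE,
                           initial = initial_condition_spec(c(A = 1, B = 0)),
                           measurement_window = 1)
  f <- run_ensemble(net, cfg)$frequency
  expect_equal(unname(f["A", ]), c(1, 0, 1, 0, 1))
  expect_equal(unname(f["B", ]), c(0, 1, 0, 1, 0))
})

test_that("ensemble export round-trips as tidy data", {
  net <- relay_net(0.5)
  res <- run_ensemble(net, simulation_config(steps = 5, repetitions = 10, seed = 1))
  df <- as.data.frame(res)
  expect_equal(nrow(df), 2 * 6)
  expect_named(df, c("node", "step", "frequency"))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_ensemble_csv(res, csv)
  expect_equal(nrow(utils::read.csv(csv)), nrow(df))
  write_ensemble_json(res, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$seed, 1)
  expect_named(parsed$end_marginals, c("A", "B"))
})
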