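params <- default_parameters()
base <- base_assignment(params)

test_that("the canonical model has two strategies of four terminals", {
  model <- build_model(params)
  count_terminals <- function(node) {
    if (node$kind == "terminal") return(1L)
    sum(vapply(node$branches, function(b) count_terminals(b$node),
               integer(1)))
  }
  expect_named(model$strategies, c("intervention", "control"))
  expect_equal(count_terminals(model$strategies$intervention), 4L)
  expect_equal(count_terminals(model$strategies$control), 4L)
  expect_error(build_model(params[-1, ]),
               "missing: cost_severe_intervention")
})

test_that("rollback reproduces the hand-expanded base-case expectations", {
  model <- build_model(params)
  out <- rollback(model, base)
  oi <- oracle_strategy_expectation(0.16, 0.85, 0.87, 25.74, 3.58)
  oc <- oracle_strategy_expectation(0.04, 0.56, 0.87, 17.98, 2.14)
  expect_equal(out$cost[out$strategy == "intervention"], oi$cost,
               tolerance = 1e-12)
  expect_equal(out$effect[out$strategy == "intervention"], oi$effect,
               tolerance = 1e-12)
  expect_equal(out$cost[out$strategy == "control"], oc$cost,
               tolerance = 1e-12)
  expect_equal(out$effect[out$strategy == "control"], oc$effect,
               tolerance = 1e-12)
  # frozen values from the same oracle
  expect_equal(out$cost, c(7.1256, 2.7736), tolerance = 1e-12)
  expect_equal(out$effect, c(0.1360, 0.0224), tolerance = 1e-12)
})

test_that("incremental analysis yields the base-case ICER per definition", {
  model <- build_model(params)
  inc <- incremental(rollback(model, base))
  expect_equal(inc$delta_cost, 4.3520, tolerance = 1e-12)
  expect_equal(inc$delta_effect, 0.1136, tolerance = 1e-12)
  expect_equal(inc$icer, 4.3520 / 0.1136, tolerance = 1e-12)
  expect_equal(inc$icer, 38.31, tolerance = 1e-4)
  expect_equal(inc$status, "icer")

  model_any <- build_model(params, "any_severe_diagnosis")
  inc_any <- incremental(rollback(model_any, base))
  expect_equal(inc_any$delta_effect, 0.12, tolerance = 1e-12)
  expect_equal(inc_any$icer, 4.3520 / 0.12, tolerance = 1e-12)
  expect_equal(inc_any$icer, 36.27, tolerance = 1e-2)
})

test_that("degenerate probability assignments collapse to single leaves", {
  model <- build_model(params)
  a <- base
  a$p_severe_intervention <- 0
  out <- rollback(model, a)
  expect_equal(out$cost[out$strategy == "intervention"],
               0.87 * 3.58 + 0.13 * 3.58)  # = non-severe cost
  expect_equal(out$effect[out$strategy == "intervention"], 0)

  a <- base
  a[c("p_severe_intervention", "sens_intervention",
      "spec_intervention")] <- list(1, 1, 1)
  out <- rollback(model, a)
  expect_equal(out$cost[out$strategy == "intervention"], 25.74)
  expect_equal(out$effect[out$strategy == "intervention"], 1)
})

test_that("perfect sensitivity makes both effect definitions coincide", {
  a <- base
  a$sens_intervention <- 1
  a$sens_control <- 1
  inc_tp <- incremental(rollback(build_model(params), a))
  inc_any <- incremental(rollback(
    build_model(params, "any_severe_diagnosis"), a))
  expect_equal(inc_tp$icer, inc_any$icer, tolerance = 1e-12)
  expect_equal(inc_tp$delta_effect, inc_any$delta_effect, tolerance = 1e-12)
})

test_that("dominance and equal-effect statuses follow the sign cases", {
  mk <- function(ci, ei, cc, ec) {
    tibble::tibble(strategy = c("intervention", "control"),
                   cost = c(ci, cc), effect = c(ei, ec))
  }
  expect_equal(incremental(mk(1, 0.5, 2, 0.2))$status, "dominant")
  expect_equal(incremental(mk(3, 0.1, 2, 0.2))$status, "dominated")
  eq <- incremental(mk(3, 0.2, 2, 0.2))
  expect_equal(eq$status, "equal_effect")
  expect_true(is.na(eq$icer))
  expect_equal(incremental(mk(3, 0.3, 2, 0.2))$status, "icer")
})

test_that("ICER is invariant to strategy evaluation order up to sign", {
  model <- build_model(params)
  out <- rollback(model, base)
  fwd <- incremental(out, comparator = "intervention", reference = "control")
  rev <- incremental(out, comparator = "control", reference = "intervention")
  expect_equal(fwd$icer, rev$icer, tolerance = 1e-12)  # ratio of two negations
  expect_equal(fwd$delta_cost, -rev$delta_cost)
})

test_that("invalid probabilities are rejected at rollback", {
  model <- build_model(params)
  a <- base
  a$p_severe_intervention <- 1.2
  expect_error(rollback(model, a), "outside \\[0, 1\\]")
  bad_node <- chance_node("n", list(
    branch(0.5, terminal_node("a", 1, 0)),
    branch(0.3, terminal_node("b", 2, 1))
  ))
  expect_error(rollback(bad_node, list()), "do not sum to 1")
  expect_error(rollback(model, base[-1]), "missing parameter")
})

test_that("rollback equals the path-enumeration oracle on random trees", {
  withr::with_seed(7, {
    for (i in 1:60) {
      tree <- random_tree(max_depth = sample(2:6, 1))
      got <- rollback(tree, list())
      want <- oracle_expectation(tree, list())
      expect_equal(got$cost, want$cost, tolerance = 1e-12)
      expect_equal(got$effect, want$effect, tolerance = 1e-12)
      # expectation bounded by the leaf payoffs
      expect_gte(got$cost, min(want$leaf_costs) - 1e-12)
      expect_lte(got$cost, max(want$leaf_costs) + 1e-12)
      expect_gte(got$effect, 0)
      expect_lte(got$effect, 1)
    }
  })
})

test_that("models serialize to a JSON tree document", {
  path <- withr::local_tempfile(fileext = ".json")
  write_model(build_model(params), path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(doc$effect_definition, "true_positive")
  expect_named(doc$strategies, c("intervention", "control"))
  expect_equal(doc$strategies$intervention$branches[[1]]$prob$param,
               "p_severe_intervention")
})
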