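test_that("validation accepts the case study and pinpoints broken models", {
  m <- build_paper_model()
  expect_length(validate_model(m), 0)

  # chance node whose probabilities sum to 1.1
  bad_params <- prob_params(
    prob_param("pa", 0.6), prob_param("pb", 0.5)
  )
  nodes <- list(
    decision_node("root", list(
      branch("n1", alternative = "usual_practice"),
      branch("t0", alternative = "intervention")
    )),
    chance_node("n1", list(
      branch("t1", prob = "pa"), branch("t2", prob = "pb")
    )),
    terminal_node("t0", "GP"), terminal_node("t1", "GP"),
    terminal_node("t2", "hospital")
  )
  broken <- cma_model(nodes, bad_params, tiny_model()$costbook, check = FALSE)
  viol <- validate_model(broken)
  expect_length(viol, 1)
  expect_match(viol, "n1")
  expect_match(viol, "1\\.1")

  # dangling cost-component reference
  dangling <- tiny_model()
  dangling$nodes$root$branches[[1]]$costs <- c("c1", "ghost_cost")
  viol <- validate_model(dangling)
  expect_length(viol, 1)
  expect_match(viol, "ghost_cost")

  # dangling probability reference
  broken2 <- broken
  broken2$nodes$n1$branches[[1]]$prob <- "missing_p"
  expect_true(any(grepl("missing_p", validate_model(broken2))))

  # both standard alternatives must be declared
  solo <- tiny_model()
  solo$nodes$root$branches <- solo$nodes$root$branches[1]
  expect_true(any(grepl("intervention", validate_model(solo))))
})

test_that("roll-back reproduces the hand path-enumeration oracle", {
  m <- build_paper_model()
  expect_equal(expected_cost(m, "usual_practice"),
               oracle_expected("usual_practice"), tolerance = 1e-12)
  expect_equal(expected_cost(m, "intervention"),
               oracle_expected("intervention"), tolerance = 1e-12)
  # full-precision values behind the rounded headline figures
  expect_equal(round(expected_cost(m, "usual_practice"), 3), 234.683)
  expect_equal(round(expected_cost(m, "intervention"), 3), 125.286)
  # healthcare perspective
  expect_equal(expected_cost(m, "usual_practice", "healthcare"),
               oracle_expected("usual_practice", "healthcare"),
               tolerance = 1e-12)
  expect_equal(round(expected_cost(m, "usual_practice", "healthcare"), 2),
               170.78)
  expect_equal(round(expected_cost(m, "intervention", "healthcare"), 2),
               93.00)
})

test_that("degenerate single-terminal tree returns its accrued cost", {
  m <- tiny_model(42)
  expect_equal(expected_cost(m, "usual_practice"), 42)
  ep <- enumerate_paths(m, "usual_practice")
  expect_equal(nrow(ep), 1)
  expect_equal(ep$probability, 1)
  expect_equal(ep$cost, 42)
})

test_that("unknown alternative errors name the valid alternatives", {
  m <- build_paper_model()
  expect_error(expected_cost(m, "standard_care"),
               "usual_practice.*intervention")
  expect_error(enumerate_paths(m, "standard_care"), "usual_practice")
})

test_that("path enumeration yields the referral-pattern probabilities", {
  m <- build_paper_model()
  up <- enumerate_paths(m, "usual_practice")
  expect_equal(sort(up$probability), sort(c(0.2116, 0.0184, 0.77)),
               tolerance = 1e-12)
  iv <- enumerate_paths(m, "intervention")
  expect_equal(sort(iv$probability),
               sort(c(0.73, 0.039744, 0.003456, 0.2268)), tolerance = 1e-12)
  expect_equal(sum(up$probability), 1, tolerance = 1e-9)
  expect_equal(sum(iv$probability), 1, tolerance = 1e-9)
  expect_equal(sum(iv$probability * iv$cost),
               expected_cost(m, "intervention"), tolerance = 1e-9)
})

test_that("incremental cost is the difference of the expected costs", {
  m <- build_paper_model()
  ev <- evaluate_model(m)
  expect_equal(incremental_cost(ev), oracle_incremental(), tolerance = 1e-12)
  expect_equal(round(incremental_cost(ev), 2), -109.40)
  expect_equal(incremental_cost(ev),
               ev$expected_cost[["intervention"]] -
                 ev$expected_cost[["usual_practice"]])
  # identical alternatives
  expect_equal(incremental_cost(evaluate_model(tiny_model())), 0)
  # healthcare perspective
  expect_equal(round(incremental_cost(scenario_healthcare(m)), 2), -77.78)
  # missing alternative errors
  ev$expected_cost <- ev$expected_cost["intervention"]
  expect_error(incremental_cost(ev), "usual_practice")
})

test_that("roll-back agrees with path enumeration on random models", {
  for (s in 1:60) {
    m <- random_model(s)
    expect_length(validate_model(m), 0)
    for (a in c("usual_practice", "intervention")) {
      ep <- enumerate_paths(m, a)
      expect_equal(sum(ep$probability), 1, tolerance = 1e-9)
      expect_equal(sum(ep$probability * ep$cost), expected_cost(m, a),
                   tolerance = 1e-9)
    }
  }
})

test_that("expected cost is affine in any component's unit price", {
  for (s in c(3, 17, 42)) {
    m <- random_model(s)
    cid <- m$costbook$id[which.max(m$costbook$quantity * m$costbook$unit_price)]
    base_cost <- m$costbook$quantity[m$costbook$id == cid] *
      m$costbook$unit_price[m$costbook$id == cid]
    for (a in c("usual_practice", "intervention")) {
      f <- function(alpha) {
        expected_cost(m, a, cost_overrides = stats::setNames(alpha * base_cost, cid))
      }
      # affine: equal increments for equal price steps
      expect_equal(f(2) - f(1), f(1) - f(0), tolerance = 1e-9)
      # slope equals component exposure (path-probability-weighted
      # multiplicity, respecting the applies_to filter) times the price
      st <- pocuscma:::path_structure(m, a)
      applies <- m$costbook$applies_to[m$costbook$id == cid] %in% c("both", a)
      probs <- stats::setNames(m$params$base, m$params$id)
      exposure <- sum(vapply(st, function(p) {
        prod(probs[p$prob_params]) * sum(p$cost_ids == cid)
      }, 0)) * as.numeric(applies)
      expect_equal(f(2) - f(1), exposure * base_cost, tolerance = 1e-9)
    }
  }
})

test_that("branch order at a chance node does not change the value", {
  m <- build_paper_model()
  base <- vapply(c("usual_practice", "intervention"), expected_cost, 0,
                 model = m)
  for (nid in names(m$nodes)) {
    if (m$nodes[[nid]]$kind != "chance") next
    m2 <- m
    m2$nodes[[nid]]$branches <- rev(m2$nodes[[nid]]$branches)
    perm <- vapply(c("usual_practice", "intervention"), expected_cost, 0,
                   model = m2)
    expect_equal(perm, base, tolerance = 1e-12)
  }
})
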