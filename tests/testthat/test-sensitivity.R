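test_that("one-way DSA endpoints match the hand oracle", {
  m <- build_paper_model()
  ow <- one_way(m, "iv_complete_gp")
  expect_equal(ow$incremental_at_low, oracle_incremental(iv_comp = 0.40),
               tolerance = 1e-12)
  expect_equal(ow$incremental_at_high, oracle_incremental(iv_comp = 0.98),
               tolerance = 1e-12)
  expect_equal(round(ow$incremental_at_low, 2), -42.05)
  expect_equal(round(ow$incremental_at_high, 2), -160.42)
  expect_equal(ow$swing, abs(ow$incremental_at_high - ow$incremental_at_low))

  # co-varied complement: varying the referral split moves both arms
  ow2 <- one_way(m, "up_refer_gyn")
  expect_equal(ow2$incremental_at_low, oracle_incremental(up_gyn = 0),
               tolerance = 1e-12)
  expect_equal(ow2$incremental_at_high, oracle_incremental(up_gyn = 1),
               tolerance = 1e-12)

  # cost parameter: the scanner price accrues on every intervention
  # patient's GP visit, so the swing is the full range width
  ow3 <- one_way(m, "gp_scanner")
  expect_equal(ow3$swing, 13.77 - 1.30, tolerance = 1e-9)
})

test_that("degenerate and invalid one-way ranges are handled", {
  m <- build_paper_model()
  ow <- one_way(m, "iv_complete_gp", range = c(0.73, 0.73))
  expect_equal(ow$swing, 0)
  expect_equal(ow$incremental_at_low, oracle_incremental(), tolerance = 1e-12)
  expect_error(one_way(m, "iv_complete_gp", range = c(-0.1, 0.9)),
               "outside \\[0, 1\\]")
  expect_error(one_way(m, "no_such_parameter"), "no_such_parameter")
})

test_that("one-way DSA of a cost parameter is affine", {
  m <- build_paper_model()
  dsa <- dsa_parameters(m)
  for (id in dsa$id[dsa$type == "cost"]) {
    row <- dsa[dsa$id == id, ]
    mid <- (row$low + row$high) / 2
    ends <- one_way(m, id)
    at_mid <- one_way(m, id, range = c(mid, mid))$incremental_at_low
    expect_equal(at_mid,
                 (ends$incremental_at_low + ends$incremental_at_high) / 2,
                 tolerance = 1e-12)
  }
})

test_that("probability perturbations keep every chance node summing to 1", {
  m <- build_paper_model()
  dsa <- dsa_parameters(m)
  for (id in dsa$id[dsa$type == "probability"]) {
    for (v in c(dsa$low[dsa$id == id], dsa$high[dsa$id == id])) {
      ov <- pocuscma:::overrides_for(m, id, v)
      probs <- pocuscma:::base_probs(m, ov$prob)
      for (nd in m$nodes) {
        if (nd$kind != "chance") next
        prefs <- vapply(nd$branches, `[[`, "", "prob")
        expect_equal(sum(probs[prefs]), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("tornado ranks completion-at-GP first with all-negative bars", {
  m <- build_paper_model()
  tw <- tornado(m)
  expect_s3_class(tw, "tornado_result")
  # every Table-3 parameter appears: 10 probabilities + 15 single cost
  # components + 1 utensil bundle
  expect_equal(nrow(tw), 26)
  expect_equal(tw$parameter[1], "iv_complete_gp")
  expect_true(all(tw$incremental_at_low < 0))
  expect_true(all(tw$incremental_at_high < 0))
  expect_true(all(diff(tw$swing) <= 1e-12))
  # the utensil bundle is varied as one parameter, members not separately
  expect_true("gp_utensils" %in% tw$parameter)
  expect_false(any(c("gp_wet_wipes", "gp_gel") %in% tw$parameter))
})

test_that("scenario analysis drops exactly the patient-borne costs", {
  m <- build_paper_model()
  hc <- scenario_healthcare(m)
  expect_equal(hc$incremental, oracle_incremental("healthcare"),
               tolerance = 1e-12)
  # a model with no patient-borne components is perspective-invariant
  t <- tiny_model()
  expect_equal(scenario_healthcare(t)$expected_cost,
               evaluate_model(t, "societal")$expected_cost)
})

test_that("beta fits preserve the mean and reject impossible moments", {
  d <- fit_beta(0.5, c(0, 1))
  expect_equal(d$alpha, 1.5)
  expect_equal(d$beta, 1.5)
  d2 <- fit_beta(0.73, c(0.40, 0.98))
  expect_equal(d2$alpha / (d2$alpha + d2$beta), 0.73, tolerance = 1e-12)
  # zero-width range degenerates to a point mass
  d3 <- fit_beta(0.4, c(0.4, 0.4))
  expect_equal(d3$family, "constant")
  expect_equal(unique(pocuscma:::draw_psa_dist(d3, 10)), 0.4)
  # variance >= m(1-m) is impossible for a beta
  expect_error(fit_beta(0.02, c(0, 1)), "narrower range")
  expect_error(fit_beta(1.2, c(0, 2)), "mean")
})

test_that("gamma fits preserve the mean", {
  d <- fit_gamma(10, c(5, 15))  # sd 2.5
  expect_equal(d$shape, 16)
  expect_equal(d$scale, 0.625)
  for (mean in c(0.5, 7.54, 164.26)) {
    for (w in c(0.5, 3)) {
      d <- fit_gamma(mean, c(mean - w / 2, mean + w / 2))
      expect_equal(d$shape * d$scale, mean, tolerance = 1e-12)
    }
  }
  set.seed(1)
  x <- pocuscma:::draw_psa_dist(fit_gamma(164.26, c(164.26, 164.79)), 10000)
  expect_lt(abs(mean(x) - 164.26) / 164.26, 0.01)
  expect_equal(fit_gamma(5, c(5, 5))$family, "constant")
  expect_error(fit_gamma(-1, c(0, 2)), "> 0")
})

test_that("the PSA is seed-reproducible and mean-preserving", {
  m <- build_paper_model()
  cfg <- psa_config(n_draws = 4000, seed = 7)
  p1 <- run_psa(m, cfg)
  p2 <- run_psa(m, cfg)
  expect_identical(summary(p1), summary(p2))
  expect_identical(p1$draws, p2$draws)
  expect_false(identical(p1$draws, run_psa(m, psa_config(4000, seed = 8))$draws))
  # summaries recomputable from the stored draws
  expect_equal(unname(summary(p1)["mean"]), p1$mean)
  expect_equal(unname(summary(p1)["fraction_cost_saving"]),
               p1$fraction_cost_saving)
  expect_gte(p1$fraction_cost_saving, 0)
  expect_lte(p1$fraction_cost_saving, 1)
  # independent mean-preserving draws keep the mean near the base case
  base <- evaluate_model(m)$incremental
  expect_lt(abs(p1$mean - base), 4 * p1$sd / sqrt(p1$n_draws))
})

test_that("a fully degenerate PSA returns the base case on every draw", {
  m <- build_paper_model()
  m$params$low <- m$params$base
  m$params$high <- m$params$base
  cb_cost <- m$costbook$quantity * m$costbook$unit_price
  m$costbook$cost_low <- ifelse(is.na(m$costbook$cost_low), NA, cb_cost)
  m$costbook$cost_high <- ifelse(is.na(m$costbook$cost_high), NA, cb_cost)
  g <- m$cost_groups$gp_utensils
  base_bundle <- sum(cb_cost[match(g$components, m$costbook$id)])
  m$cost_groups$gp_utensils$low <- base_bundle
  m$cost_groups$gp_utensils$high <- base_bundle
  p <- run_psa(m, psa_config(50, seed = 3))
  expect_equal(unique(round(p$draws, 9)), round(evaluate_model(m)$incremental, 9))
  expect_equal(p$sd, 0)
})

test_that("vectorised PSA evaluation agrees with per-draw roll-back", {
  m <- build_paper_model()
  set.seed(99)
  n <- 8
  P <- matrix(rep(m$params$base, each = n), nrow = n,
              dimnames = list(NULL, m$params$id))
  # jitter one sampled member per complement group, partner = complement
  for (pid in m$params$id[m$params$psa_sampled]) {
    P[, pid] <- pmin(pmax(m$params$base[m$params$id == pid] +
                            stats::runif(n, -0.05, 0.05), 0), 1)
    partner <- pocuscma:::complement_partner(m$params, pid)
    P[, partner] <- 1 - P[, pid]
  }
  base_costs <- m$costbook$quantity * m$costbook$unit_price
  C <- matrix(rep(base_costs, each = n), nrow = n,
              dimnames = list(NULL, m$costbook$id))
  C[, "hosp_tariff"] <- base_costs[m$costbook$id == "hosp_tariff"] *
    stats::runif(n, 0.8, 1.2)
  vec <- pocuscma:::psa_incremental(m, P, C)
  loop <- vapply(seq_len(n), function(i) {
    evaluate_model(m, prob_overrides = P[i, ],
                   cost_overrides = C[i, ])$incremental
  }, 0)
  expect_equal(vec, loop, tolerance = 1e-9)
})

test_that("excluded parameters are held at base during the PSA", {
  m <- build_paper_model()
  all_ids <- dsa_parameters(m)$id
  p <- run_psa(m, psa_config(20, seed = 5, excluded_ids = all_ids))
  expect_equal(unique(round(p$draws, 9)),
               round(evaluate_model(m)$incremental, 9))
})
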