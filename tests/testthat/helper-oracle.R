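# Independent hand path-enumeration oracle for the bundled case study.
# Everything here is literal arithmetic from the printed resource-use and
# unit-price tables; it never calls the tree engine.

OR_PATIENT_MIN <- 0.408 # EUR per minute of patient time
OR_KM <- 0.473          # EUR per km
OR_SCAN_MIN <- 1.807    # EUR per minute of GP scanning time

oracle_visit_costs <- function(perspective = "societal") {
  pat <- function(x) if (perspective == "societal") x else 0
  list(
    gp_usual = 19.02 +
      pat(15 * OR_PATIENT_MIN + 9.5 * OR_KM + 11 * OR_PATIENT_MIN),
    gp_int = 19.02 + 10 * OR_SCAN_MIN + 7.54 + 5.81 +
      2 * 0.054 + 0.24 + 10 * 0.021 +
      pat(25 * OR_PATIENT_MIN + 9.5 * OR_KM + 11 * OR_PATIENT_MIN),
    gyn = 96.78 +
      pat(25 * OR_PATIENT_MIN + 39.2 * OR_KM + 47 * OR_PATIENT_MIN),
    hosp = 164.26 +
      pat(25 * OR_PATIENT_MIN + 39.2 * OR_KM + 47 * OR_PATIENT_MIN)
  )
}

# Explicit enumeration of the 3 usual-practice and 4 intervention paths.
oracle_expected <- function(alternative, perspective = "societal",
                            up_gyn = 0.23, up_comp = 0.92,
                            iv_comp = 0.73, iv_gyn = 0.16,
                            iv_gyncomp = 0.92) {
  cs <- oracle_visit_costs(perspective)
  if (alternative == "usual_practice") {
    probs <- c(up_gyn * up_comp, up_gyn * (1 - up_comp), 1 - up_gyn)
    costs <- c(cs$gp_usual + cs$gyn,
               cs$gp_usual + cs$gyn + cs$hosp,
               cs$gp_usual + cs$hosp)
  } else {
    refer <- 1 - iv_comp
    probs <- c(iv_comp,
               refer * iv_gyn * iv_gyncomp,
               refer * iv_gyn * (1 - iv_gyncomp),
               refer * (1 - iv_gyn))
    costs <- c(cs$gp_int,
               cs$gp_int + cs$gyn,
               cs$gp_int + cs$gyn + cs$hosp,
               cs$gp_int + cs$hosp)
  }
  sum(probs * costs)
}

oracle_incremental <- function(perspective = "societal", ...) {
  oracle_expected("intervention", perspective, ...) -
    oracle_expected("usual_practice", perspective, ...)
}

# Minimal degenerate model: each alternative is a single terminal with
# one accrued cost component.
tiny_model <- function(cost = 42) {
  cb <- cost_components(
    cost_component("c1", "single component", "GP", "healthcare", 1, cost)
  )
  nodes <- list(
    decision_node("root", list(
      branch("t_up", alternative = "usual_practice", costs = "c1"),
      branch("t_iv", alternative = "intervention", costs = "c1")
    )),
    terminal_node("t_up", "GP"),
    terminal_node("t_iv", "GP")
  )
  cma_model(nodes, prob_params(), cb)
}
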