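# Unit prices behind the composite components. These are model constants
# (never sampled in the PSA): patient time and mileage are valued as loss
# of earnings / travel compensation, GP scanning time as a tariff.
unit_price_patient_minute <- 0.408 # EUR per minute of patient time
unit_price_km             <- 0.473 # EUR per km travelled
unit_price_gp_scan_minute <- 1.807 # EUR per minute of GP scanning time

#' Build the bundled early-pregnancy POCUS case study
#'
#' Returns the full decision model for point-of-care ultrasonography in
#' general practice for vaginal bleeding in early pregnancy: a decision
#' node over `usual_practice` (GP without POCUS refers every patient to
#' a private gynaecologist or hospital gynaecology department) and
#' `intervention` (GP with POCUS completes most patients in-house), with
#' referral probabilities from a GP questionnaire and a national
#' specialist-modernisation report, and costs per visit at each location
#' (tariffs, the POCUS add-on, patient time and transport) with their
#' plausible ranges for sensitivity analysis.
#'
#' The annuitised per-scan prices of the scanner (EUR 7.54) and the
#' POCUS training course (EUR 5.81) are stored directly as unit prices;
#' the annuity specifications that generate them are attached under
#' `$annuities` (the scanner's use fraction there is back-solved from
#' the per-scan price, as the share of scans attributable to this
#' indication is not observable).
#'
#' @return A validated `cma_model`.
#' @examples
#' m <- build_paper_model()
#' evaluate_model(m)
#' @export
build_paper_model <- function() {
  params <- prob_params(
    # usual practice: GP refers everyone; split GP -> specialist
    prob_param("up_refer_gyn", 0.23, 0, 1, "up_gp_split", TRUE,
               "questionnaire"),
    prob_param("up_gyn_complete", 0.92, 0.92, 1, "up_gyn_split", TRUE,
               "specialist modernisation report"),
    prob_param("up_gyn_refer_hosp", 0.08, 0, 0.08, "up_gyn_split", FALSE,
               "specialist modernisation report"),
    prob_param("up_refer_hosp", 0.77, 0, 1, "up_gp_split", FALSE,
               "questionnaire"),
    # intervention: GP completes or refers; then as in usual practice
    prob_param("iv_complete_gp", 0.73, 0.40, 0.98, "iv_gp_split", TRUE,
               "questionnaire"),
    prob_param("iv_refer", 0.27, 0.02, 0.60, "iv_gp_split", FALSE,
               "questionnaire"),
    prob_param("iv_refer_gyn", 0.16, 0, 1, "iv_ref_split", TRUE,
               "questionnaire"),
    prob_param("iv_gyn_complete", 0.92, 0.92, 1, "iv_gyn_split", TRUE,
               "specialist modernisation report"),
    prob_param("iv_gyn_refer_hosp", 0.08, 0, 0.08, "iv_gyn_split", FALSE,
               "specialist modernisation report"),
    prob_param("iv_refer_hosp", 0.84, 0, 1, "iv_ref_split", FALSE,
               "questionnaire")
  )

  pm <- unit_price_patient_minute
  km <- unit_price_km
  costbook <- cost_components(
    # --- general practitioner -------------------------------------------
    cost_component("gp_tariff", "Tariff for consultation (GP)",
                   "GP", "healthcare", 1, 19.02, "both", 19.02, 19.25),
    cost_component("gp_scan_time", "Time consumption for performing ultrasonography",
                   "GP", "healthcare", 10, unit_price_gp_scan_minute,
                   "intervention"),
    cost_component("gp_scanner", "Ultrasonography scanner (per scan)",
                   "GP", "healthcare", 1, 7.54, "intervention", 1.30, 13.77),
    cost_component("gp_training", "POCUS training course (per scan)",
                   "GP", "healthcare", 1, 5.81, "intervention", 3.35, 5.81),
    cost_component("gp_wet_wipes", "Utensils: wet wipes",
                   "GP", "healthcare", 2, 0.054, "intervention"),
    cost_component("gp_transducer_cover", "Utensils: transducer cover",
                   "GP", "healthcare", 1, 0.24, "intervention"),
    cost_component("gp_gel", "Utensils: gel",
                   "GP", "healthcare", 10, 0.021, "intervention"),
    # --- specialists ----------------------------------------------------
    cost_component("gyn_tariff", "Tariff for consultation with ultrasonography (private gynaecologist)",
                   "private_gynaecologist", "healthcare", 1, 96.78, "both",
                   96.78, 97.99),
    cost_component("hosp_tariff", "DRG tariff for ultrasonography (hospital)",
                   "hospital", "healthcare", 1, 164.26, "both",
                   164.26, 164.79),
    # --- patient time (minutes x EUR/min; ranges stated in minutes) -----
    cost_component("pt_time_gp_usual", "Patient time: GP without ultrasonography",
                   "GP", "patient", 15, pm, "usual_practice",
                   5 * pm, 15 * pm),
    cost_component("pt_time_gp_pocus", "Patient time: GP with ultrasonography",
                   "GP", "patient", 25, pm, "intervention",
                   13 * pm, 26 * pm),
    cost_component("pt_time_gyn", "Patient time: private gynaecologist",
                   "private_gynaecologist", "patient", 25, pm, "both",
                   13 * pm, 26 * pm),
    cost_component("pt_time_hosp", "Patient time: hospital",
                   "hospital", "patient", 25, pm, "both",
                   13 * pm, 26 * pm),
    # --- transport distance (km x EUR/km; ranges stated in km) ----------
    cost_component("travel_dist_gp", "Transport distance: GP",
                   "GP", "patient", 9.5, km, "both", 0.2 * km, 42 * km),
    cost_component("travel_dist_gyn", "Transport distance: private gynaecologist",
                   "private_gynaecologist", "patient", 39.2, km, "both",
                   0.2 * km, 100 * km),
    cost_component("travel_dist_hosp", "Transport distance: hospital",
                   "hospital", "patient", 39.2, km, "both",
                   0.2 * km, 100 * km),
    # --- transport time (minutes; printed base values, 50 km/h rule) ----
    cost_component("travel_time_gp", "Transport time: GP",
                   "GP", "patient", 11, pm, "both", 0.24 * pm, 50.40 * pm),
    cost_component("travel_time_gyn", "Transport time: private gynaecologist",
                   "private_gynaecologist", "patient", 47, pm, "both",
                   0.24 * pm, 120 * pm),
    cost_component("travel_time_hosp", "Transport time: hospital",
                   "hospital", "patient", 47, pm, "both", 0.24 * pm, 120 * pm)
  )

  gp_costs <- costbook$id[costbook$location == "GP"]
  gyn_costs <- costbook$id[costbook$location == "private_gynaecologist"]
  hosp_costs <- costbook$id[costbook$location == "hospital"]

  tree <- list(
    decision_node("root", list(
      branch("up_gp", alternative = "usual_practice", costs = gp_costs),
      branch("iv_gp", alternative = "intervention", costs = gp_costs)
    )),
    # usual practice: GP refers every patient
    chance_node("up_gp", list(
      branch("up_gyn", prob = "up_refer_gyn", costs = gyn_costs),
      branch("up_hosp_end", prob = "up_refer_hosp", costs = hosp_costs)
    )),
    chance_node("up_gyn", list(
      branch("up_gyn_end", prob = "up_gyn_complete"),
      branch("up_gyn_hosp_end", prob = "up_gyn_refer_hosp",
             costs = hosp_costs)
    )),
    terminal_node("up_gyn_end", "private_gynaecologist"),
    terminal_node("up_gyn_hosp_end", "hospital"),
    terminal_node("up_hosp_end", "hospital"),
    # intervention: GP completes or refers on
    chance_node("iv_gp", list(
      branch("iv_gp_end", prob = "iv_complete_gp"),
      branch("iv_referral", prob = "iv_refer")
    )),
    terminal_node("iv_gp_end", "GP"),
    chance_node("iv_referral", list(
      branch("iv_gyn", prob = "iv_refer_gyn", costs = gyn_costs),
      branch("iv_hosp_end", prob = "iv_refer_hosp", costs = hosp_costs)
    )),
    terminal_node("iv_hosp_end", "hospital"),
    chance_node("iv_gyn", list(
      branch("iv_gyn_end", prob = "iv_gyn_complete"),
      branch("iv_gyn_hosp_end", prob = "iv_gyn_refer_hosp",
             costs = hosp_costs)
    )),
    terminal_node("iv_gyn_end", "private_gynaecologist"),
    terminal_node("iv_gyn_hosp_end", "hospital")
  )

  cost_groups <- list(
    gp_utensils = list(
      components = c("gp_wet_wipes", "gp_transducer_cover", "gp_gel"),
      low = 0.34, high = 0.56
    )
  )

  annuities <- list(
    # training: course price over 6 course categories x 4 gynaecology
    # subcategories (heartbeat share), 7-year lifespan, 4% interest,
    # 2.4 scans/GP/year
    gp_training = annuity_spec(capital = 2008 / 6 / 4, lifespan_years = 7,
                               annual_rate = 0.04, annual_uses = 2.4),
    # scanner: purchase price 15,508.70 EUR; use_fraction (share of the
    # scanner's use attributable to early-pregnancy bleeding) is
    # back-solved from the per-scan price of 7.54 EUR -- synthetic, the
    # true share is not observable
    gp_scanner = annuity_spec(capital = 15508.70, lifespan_years = 7,
                              annual_rate = 0.04, annual_uses = 2.4,
                              use_fraction = 0.0070034)
  )

  cma_model(tree, params, costbook, cost_groups = cost_groups,
            annuities = annuities,
            settings = list(perspective = "societal", n_draws = 10000,
                            seed = 2019))
}

#' Questionnaire panel of per-GP probability estimates
#'
#' The referral probabilities of the case study were elicited by asking
#' a panel of GPs (21 POCUS users of 22 respondents) how they would
#' refer patients with and without POCUS access; per question, the model
#' uses the arithmetic mean as the base value and the lowest/highest
#' stated probability as the sensitivity range.
#'
#' @param responses data.frame with columns `question`, `gp`, `response`
#'   (each response a probability in `[0, 1]`).
#' @return A `questionnaire_panel` object.
#' @export
questionnaire_panel <- function(responses) {
  stopifnot(all(c("question", "gp", "response") %in% names(responses)))
  if (any(responses$response < 0 | responses$response > 1)) {
    stop("responses must be probabilities in [0, 1]", call. = FALSE)
  }
  structure(list(responses = responses,
                 n_gps = length(unique(responses$gp))),
            class = "questionnaire_panel")
}

#' Aggregate a questionnaire panel to model inputs
#'
#' @param panel A [questionnaire_panel()].
#' @return data.frame with one row per question: `question`, `mean`
#'   (arithmetic mean response), `low`/`high` (minimum and maximum
#'   stated response), `n` (number of responses).
#' @export
aggregate_questionnaire <- function(panel) {
  stopifnot(inherits(panel, "questionnaire_panel"))
  r <- panel$responses
  if (!nrow(r)) stop("empty panel: no responses to aggregate", call. = FALSE)
  qs <- unique(r$question)
  out <- do.call(rbind, lapply(qs, function(q) {
    x <- r$response[r$question == q]
    data.frame(question = q, mean = mean(x), low = min(x), high = max(x),
               n = length(x), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a panel of GP questionnaire responses
#'
#' Generates independent beta-distributed probability estimates with a
#' requested mean and dispersion, emulating the elicitation that
#' produced the case study's referral probabilities. Dispersion zero
#' yields a degenerate panel where every GP states the true mean.
#'
#' @param n_gps Number of responding GPs.
#' @param true_mean True mean probability, in `(0, 1)`.
#' @param dispersion Standard deviation of responses; must satisfy
#'   `dispersion^2 < true_mean * (1 - true_mean)`.
#' @param seed Integer seed.
#' @param question Question label (default `"q1"`).
#' @return A [questionnaire_panel()].
#' @examples
#' p <- simulate_gp_responses(21, 0.73, 0.15, seed = 7)
#' aggregate_questionnaire(p)
#' @export
simulate_gp_responses <- function(n_gps, true_mean, dispersion, seed,
                                  question = "q1") {
  stopifnot(n_gps >= 1, true_mean > 0, true_mean < 1, dispersion >= 0)
  set.seed(seed)
  if (dispersion == 0) {
    x <- rep(true_mean, n_gps)
  } else {
    sh <- beta_from_moments(true_mean, dispersion)
    x <- stats::rbeta(n_gps, sh$alpha, sh$beta)
  }
  questionnaire_panel(data.frame(question = question, gp = seq_len(n_gps),
                                 response = x, stringsAsFactors = FALSE))
}

#' Generate a random valid model for property testing
#'
#' Builds a random decision tree with the two standard alternatives,
#' chance nodes whose branch probabilities are Dirichlet-normalised
#' (binary nodes get a complement group), random terminal locations, and
#' a random costbook with non-negative component costs, random bearer
#' and applies_to tags. The result always passes [validate_model()].
#'
#' @param seed Integer seed; reproducible.
#' @param max_depth Maximum number of chance-node levels (`>= 1`; at
#'   depth 1 both alternatives are single terminals).
#' @param max_branching Maximum branches per chance node (`>= 2`).
#' @return A validated `cma_model`.
#' @export
random_model <- function(seed, max_depth = 3, max_branching = 3) {
  stopifnot(max_depth >= 1, max_branching >= 2)
  set.seed(seed)

  n_comp <- sample(4:9, 1)
  costbook <- do.call(cost_components, lapply(seq_len(n_comp), function(i) {
    cost_component(
      id = sprintf("c%02d", i), label = sprintf("component %d", i),
      location = sample(valid_locations, 1),
      bearer = sample(c("healthcare", "patient"), 1),
      quantity = round(stats::runif(1, 0, 50), 2),
      unit_price = round(stats::runif(1, 0, 20), 3),
      applies_to = sample(c("both", "usual_practice", "intervention"), 1)
    )
  }))

  env <- new.env()
  env$n <- 0L
  env$nodes <- list()
  env$params <- list()
  fresh_id <- function(prefix) {
    env$n <- env$n + 1L
    sprintf("%s%03d", prefix, env$n)
  }
  random_costs <- function() {
    k <- min(stats::rpois(1, 1.2), n_comp)
    if (k == 0) character() else sample(costbook$id, k)
  }
  grow <- function(depth) {
    if (depth >= max_depth || stats::runif(1) < 0.3) {
      id <- fresh_id("t")
      env$nodes[[id]] <- terminal_node(id, sample(valid_locations, 1))
      return(id)
    }
    id <- fresh_id("n")
    k <- sample(2:max_branching, 1)
    if (k == 2) {
      p1 <- stats::runif(1, 0.05, 0.95)
      probs <- c(p1, 1 - p1)
      grp <- paste0("g_", id)
    } else {
      g <- stats::rgamma(k, 1)
      probs <- g / sum(g)
      grp <- NA_character_
    }
    pids <- character(k)
    for (j in seq_len(k)) {
      pid <- fresh_id("p")
      env$params[[pid]] <- prob_param(pid, probs[j],
                                      complement_group = grp,
                                      psa_sampled = (j == 1L),
                                      source = "synthetic")
      pids[j] <- pid
    }
    branches <- lapply(seq_len(k), function(j) {
      branch(grow(depth + 1), prob = pids[j], costs = random_costs())
    })
    env$nodes[[id]] <- chance_node(id, branches)
    id
  }

  up_child <- grow(1)
  iv_child <- grow(1)
  env$nodes[["root"]] <- decision_node("root", list(
    branch(up_child, alternative = "usual_practice", costs = random_costs()),
    branch(iv_child, alternative = "intervention", costs = random_costs())
  ))

  cma_model(unname(env$nodes), do.call(prob_params, unname(env$params)),
            costbook,
            settings = list(perspective = "societal", seed = seed))
}
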