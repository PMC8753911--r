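#' Enumerate the model's sensitivity parameters
#'
#' Every probability parameter with a stated range is a one-way
#' sensitivity parameter; so is every cost component with a per-visit
#' cost range, and every cost group (a bundle such as the utensils --
#' wet wipes, transducer cover and gel -- varied as a single parameter
#' on its summed cost). Components that belong to a group are varied
#' through the group, never individually.
#'
#' @param model A `cma_model`.
#' @return data.frame with columns `id`, `type` (`"probability"` or
#'   `"cost"`), `base`, `low`, `high`, in declaration order.
#' @export
dsa_parameters <- function(model) {
  p <- model$params
  pp <- p[!is.na(p$low) & !is.na(p$high), , drop = FALSE]
  prob <- data.frame(id = pp$id, type = rep("probability", nrow(pp)),
                     base = pp$base, low = pp$low, high = pp$high,
                     stringsAsFactors = FALSE)
  grouped <- unlist(lapply(model$cost_groups, `[[`, "components"))
  cb <- model$costbook
  cc <- cb[!is.na(cb$cost_low) & !is.na(cb$cost_high) &
             !cb$id %in% grouped, , drop = FALSE]
  cost <- data.frame(id = cc$id, type = rep("cost", nrow(cc)),
                     base = cc$quantity * cc$unit_price,
                     low = cc$cost_low, high = cc$cost_high,
                     stringsAsFactors = FALSE)
  grp <- do.call(rbind, lapply(names(model$cost_groups), function(g) {
    spec <- model$cost_groups[[g]]
    members <- cb[match(spec$components, cb$id), ]
    data.frame(id = g, type = "cost",
               base = sum(members$quantity * members$unit_price),
               low = spec$low, high = spec$high, stringsAsFactors = FALSE)
  }))
  out <- rbind(prob, cost, grp)
  rownames(out) <- NULL
  out
}

complement_partner <- function(params, id) {
  g <- params$complement_group[params$id == id]
  if (is.na(g)) return(NA_character_)
  setdiff(params$id[!is.na(params$complement_group) &
                      params$complement_group == g], id)
}

# Named override vectors realising "parameter <id> takes value <v>":
# probabilities co-vary their complement partner (clamped to [0, 1]);
# cost groups scale their member components so the bundle sums to v.
overrides_for <- function(model, id, v) {
  p <- model$params
  if (id %in% p$id) {
    po <- stats::setNames(v, id)
    partner <- complement_partner(p, id)
    if (!is.na(partner) && length(partner)) {
      po[partner] <- min(max(1 - v, 0), 1)
    }
    return(list(prob = po, cost = NULL))
  }
  if (id %in% names(model$cost_groups)) {
    spec <- model$cost_groups[[id]]
    members <- model$costbook[match(spec$components, model$costbook$id), ]
    base <- members$quantity * members$unit_price
    ratio <- if (sum(base) > 0) v / sum(base) else 0
    return(list(prob = NULL,
                cost = stats::setNames(base * ratio, members$id)))
  }
  if (id %in% model$costbook$id) {
    return(list(prob = NULL, cost = stats::setNames(v, id)))
  }
  stop(sprintf("unknown sensitivity parameter '%s'", id), call. = FALSE)
}

#' One-way deterministic sensitivity analysis of a single parameter
#'
#' Re-evaluates the societal incremental cost with the parameter set to
#' each end of its plausible range, all other parameters held at base.
#' A probability parameter's complement-group partner is co-varied so
#' the chance node still sums to 1 (clamped at the degenerate endpoints
#' 0 and 1).
#'
#' @param model A `cma_model`.
#' @param parameter_id A parameter listed by [dsa_parameters()].
#' @param range Optional `c(low, high)` overriding the stored range.
#' @return A one-row data.frame: `parameter`, `low`, `high`,
#'   `incremental_at_low`, `incremental_at_high`, `swing` (absolute
#'   difference of the endpoint incrementals).
#' @export
one_way <- function(model, parameter_id, range = NULL) {
  dsa <- dsa_parameters(model)
  row <- dsa[dsa$id == parameter_id, ]
  if (is.null(range)) {
    if (!nrow(row)) {
      stop(sprintf("parameter '%s' has no sensitivity range", parameter_id),
           call. = FALSE)
    }
    range <- c(row$low, row$high)
  }
  if (range[1] > range[2]) stop("range must satisfy low <= high", call. = FALSE)
  is_prob <- parameter_id %in% model$params$id
  if (is_prob && (range[1] < 0 || range[2] > 1)) {
    stop(sprintf("range [%s, %s] for probability parameter '%s' is outside [0, 1]",
                 format(range[1]), format(range[2]), parameter_id),
         call. = FALSE)
  }
  inc_at <- function(v) {
    ov <- overrides_for(model, parameter_id, v)
    evaluate_model(model, "societal", prob_overrides = ov$prob,
                   cost_overrides = ov$cost)$incremental
  }
  lo <- inc_at(range[1])
  hi <- inc_at(range[2])
  data.frame(parameter = parameter_id, low = range[1], high = range[2],
             incremental_at_low = lo, incremental_at_high = hi,
             swing = abs(hi - lo), stringsAsFactors = FALSE)
}

#' Tornado analysis: one-way DSA over all ranged parameters
#'
#' Runs [one_way()] for every parameter listed by [dsa_parameters()] and
#' ranks the entries by swing, widest first (ties keep declaration
#' order), as plotted in a tornado diagram.
#'
#' @param model A `cma_model`.
#' @return A `tornado_result` data.frame (columns as in [one_way()]),
#'   sorted by decreasing swing.
#' @examples
#' head(tornado(build_paper_model()), 3)
#' @export
tornado <- function(model) {
  dsa <- dsa_parameters(model)
  out <- do.call(rbind, lapply(dsa$id, one_way, model = model))
  out <- out[order(-out$swing), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' Scenario analysis: healthcare-sector perspective
#'
#' Re-evaluates the model counting only costs borne by the healthcare
#' sector (consultation tariffs and the POCUS add-on), excluding patient
#' time and transport.
#'
#' @param model A `cma_model`.
#' @return An `evaluation_result` under the healthcare perspective.
#' @examples
#' scenario_healthcare(build_paper_model())  # saving rounds to EUR 78
#' @export
scenario_healthcare <- function(model) {
  evaluate_model(model, "healthcare")
}

beta_from_moments <- function(mean, sd) {
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop(sprintf(
      "beta fit impossible: variance %.6g >= mean*(1-mean) = %.6g; use a narrower range",
      v, mean * (1 - mean)), call. = FALSE)
  }
  alpha <- mean * (mean * (1 - mean) / v - 1)
  list(alpha = alpha, beta = alpha * (1 - mean) / mean)
}

#' Method-of-moments beta fit for a probability parameter
#'
#' Fits a beta distribution with the parameter's base value as its mean
#' and standard deviation `(high - low) / 4`, treating the plausible
#' range as roughly a +/-2 sd interval: `alpha = m (m(1-m)/v - 1)`,
#' `beta = alpha (1-m)/m`. A zero-width range yields a point mass.
#'
#' @param mean Base-case probability, in `(0, 1)` for a proper beta.
#' @param range `c(low, high)` with `low <= mean <= high`.
#' @return A `psa_dist` list: `family` (`"beta"` or `"constant"`) with
#'   shape parameters or the constant value; the fitted mean is exact.
#' @examples
#' fit_beta(0.5, c(0, 1))  # alpha = beta = 1.5
#' @export
fit_beta <- function(mean, range) {
  stopifnot(length(range) == 2L, range[1] <= range[2])
  if (range[1] == range[2]) {
    return(structure(list(family = "constant", value = mean, mean = mean),
                     class = "psa_dist"))
  }
  if (mean <= 0 || mean >= 1) stop("mean must be in (0, 1)", call. = FALSE)
  if (mean < range[1] || mean > range[2]) {
    stop("mean must lie inside the range", call. = FALSE)
  }
  sh <- beta_from_moments(mean, (range[2] - range[1]) / 4)
  structure(list(family = "beta", alpha = sh$alpha, beta = sh$beta,
                 mean = mean), class = "psa_dist")
}

#' Method-of-moments gamma fit for a cost parameter
#'
#' Fits a gamma distribution with the component's base-case cost as its
#' mean and standard deviation `(high - low) / 4`: `shape = m^2 / v`,
#' `scale = v / m`. A zero-width range yields a point mass.
#'
#' @param mean Base-case cost in EUR, `> 0` for a proper gamma.
#' @param range `c(low, high)` in EUR, `low <= high`.
#' @return A `psa_dist` list (`family` `"gamma"` or `"constant"`); the
#'   fitted mean is exact (`shape * scale = mean`).
#' @examples
#' fit_gamma(10, c(5, 15))  # sd 2.5: shape 16, scale 0.625
#' @export
fit_gamma <- function(mean, range) {
  stopifnot(length(range) == 2L, range[1] <= range[2])
  if (range[1] == range[2]) {
    return(structure(list(family = "constant", value = mean, mean = mean),
                     class = "psa_dist"))
  }
  if (mean <= 0) stop("mean must be > 0", call. = FALSE)
  v <- ((range[2] - range[1]) / 4)^2
  structure(list(family = "gamma", shape = mean^2 / v, scale = v / mean,
                 mean = mean), class = "psa_dist")
}

draw_psa_dist <- function(d, n) {
  switch(d$family,
    constant = rep(d$value, n),
    beta = stats::rbeta(n, d$alpha, d$beta),
    gamma = stats::rgamma(n, shape = d$shape, scale = d$scale),
    stop("unknown distribution family ", d$family, call. = FALSE)
  )
}

#' Configuration of the probabilistic sensitivity analysis
#'
#' @param n_draws Number of Monte Carlo draws (base case: 10,000).
#' @param seed Integer seed; identical configurations reproduce
#'   byte-identical results.
#' @param excluded_ids Sensitivity-parameter identifiers held at base
#'   during the PSA. The unit prices for mileage, GP scanning time and
#'   patient time are constants of the model (not sampled parameters),
#'   so they are excluded by construction.
#' @return A `psa_config` list.
#' @export
psa_config <- function(n_draws = 10000, seed = 1L,
                       excluded_ids = character()) {
  stopifnot(n_draws >= 1)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 excluded_ids = excluded_ids), class = "psa_config")
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Draws all included parameters jointly and independently -- beta
#' distributions for probabilities, gamma for costs, both fitted by the
#' method of moments ([fit_beta()], [fit_gamma()]) -- and re-evaluates
#' the societal incremental cost for every draw. In each complement
#' group exactly one member (flagged `psa_sampled`) is drawn and its
#' partner set to the complement, so chance nodes always sum to 1. Cost
#' groups are drawn on the bundle cost and spread proportionally over
#' their members.
#'
#' @param model A `cma_model`.
#' @param config A [psa_config()].
#' @return A `psa_result` list: `draws` (incremental cost per draw, EUR),
#'   `mean`, `sd`, `q025`, `q975`, `fraction_cost_saving` (share of
#'   draws with incremental < 0), `n_draws`, `seed`, `excluded_ids`.
#' @examples
#' run_psa(build_paper_model(), psa_config(n_draws = 500, seed = 42))
#' @export
run_psa <- function(model, config = psa_config()) {
  stopifnot(inherits(config, "psa_config"))
  n <- config$n_draws
  params <- model$params
  dsa <- dsa_parameters(model)
  excl <- config$excluded_ids

  sampled_prob <- params$id[params$psa_sampled & !is.na(params$low) &
                              !params$id %in% excl]
  cost_ids <- dsa$id[dsa$type == "cost" & !dsa$id %in% excl]

  set.seed(config$seed)
  # probability draws: matrix over ALL parameters, base-filled
  P <- matrix(rep(params$base, each = n), nrow = n,
              dimnames = list(NULL, params$id))
  for (pid in sampled_prob) {
    row <- params[params$id == pid, ]
    P[, pid] <- draw_psa_dist(fit_beta(row$base, c(row$low, row$high)), n)
    partner <- complement_partner(params, pid)
    if (!is.na(partner) && length(partner)) P[, partner] <- 1 - P[, pid]
  }
  # cost draws: matrix of per-visit component costs, base-filled
  cb <- model$costbook
  C <- matrix(rep(cb$quantity * cb$unit_price, each = n), nrow = n,
              dimnames = list(NULL, cb$id))
  for (cid in cost_ids) {
    row <- dsa[dsa$id == cid, ]
    draws <- draw_psa_dist(fit_gamma(row$base, c(row$low, row$high)), n)
    if (cid %in% names(model$cost_groups)) {
      members <- model$cost_groups[[cid]]$components
      base <- cb$quantity[match(members, cb$id)] *
        cb$unit_price[match(members, cb$id)]
      ratio <- draws / sum(base)
      for (m_id in members) C[, m_id] <- base[match(m_id, members)] * ratio
    } else {
      C[, cid] <- draws
    }
  }

  inc <- psa_incremental(model, P, C, perspective = "societal")

  structure(
    list(draws = inc, mean = mean(inc), sd = stats::sd(inc),
         q025 = unname(stats::quantile(inc, 0.025)),
         q975 = unname(stats::quantile(inc, 0.975)),
         fraction_cost_saving = mean(inc < 0),
         n_draws = n, seed = config$seed, excluded_ids = excl),
    class = "psa_result"
  )
}

# Vectorised evaluation over draw matrices: for each alternative, the
# expected cost of a draw is the sum over root-to-terminal paths of
# (product of that draw's branch probabilities) x (sum of that draw's
# accrued component costs). Exact restatement of the roll-back because
# the model is a finite tree.
psa_incremental <- function(model, P, C, perspective = "societal") {
  ec_alt <- function(alternative) {
    keep <- (model$costbook$applies_to == "both" |
               model$costbook$applies_to == alternative)
    if (perspective == "healthcare") {
      keep <- keep & model$costbook$bearer == "healthcare"
    }
    Ca <- C
    Ca[, !keep] <- 0
    st <- path_structure(model, alternative)
    total <- 0
    for (p in st) {
      prob <- rep(1, nrow(P))
      for (pid in p$prob_params) prob <- prob * P[, pid]
      cost <- rep(0, nrow(C))
      for (cid in p$cost_ids) cost <- cost + Ca[, cid]
      total <- total + prob * cost
    }
    total
  }
  ec_alt("intervention") - ec_alt("usual_practice")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws, seed %d\n", x$n_draws, x$seed))
  cat(sprintf("  incremental cost: mean EUR %.2f (sd %.2f), 95%% CI [%.2f, %.2f]\n",
              x$mean, x$sd, x$q025, x$q975))
  cat(sprintf("  fraction of draws cost-saving: %.4f\n",
              x$fraction_cost_saving))
  invisible(x)
}

#' Recompute the summary statistics of a PSA result from its draws
#'
#' @param object A `psa_result`.
#' @param ... Unused.
#' @return Named numeric vector (`mean`, `sd`, `q025`, `q975`,
#'   `fraction_cost_saving`).
#' @export
summary.psa_result <- function(object, ...) {
  d <- object$draws
  c(mean = mean(d), sd = stats::sd(d),
    q025 = unname(stats::quantile(d, 0.025)),
    q975 = unname(stats::quantile(d, 0.975)),
    fraction_cost_saving = mean(d < 0))
}
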