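#' Probability parameters
#'
#' A probability parameter carries a base value (the model mean), an
#' optional plausible range for the deterministic sensitivity analysis
#' (DSA), an optional complement group linking the two branch
#' probabilities of a binary chance node (so perturbing one co-varies the
#' other to keep the node summing to 1), and a flag marking which member
#' of the group is the one sampled in the probabilistic sensitivity
#' analysis (its partner is set to the complement of the draw).
#'
#' @param id Identifier.
#' @param base Probability in `[0, 1]`.
#' @param low,high DSA range, `low <= base <= high`, inside `[0, 1]`;
#'   `NA` if the parameter has no range.
#' @param complement_group Optional group identifier shared by the two
#'   probabilities of a binary chance node.
#' @param psa_sampled `TRUE` for the member of a complement group drawn in
#'   the PSA (exactly one per group), and for any ungrouped parameter that
#'   should be sampled.
#' @param source Free-text provenance label.
#' @return `prob_param()` returns a one-row data.frame; `prob_params()`
#'   binds its `...` arguments into the parameter table of a
#'   [cma_model()].
#' @export
prob_param <- function(id, base, low = NA_real_, high = NA_real_,
                       complement_group = NA_character_,
                       psa_sampled = FALSE, source = "") {
  data.frame(id = id, base = base, low = low, high = high,
             complement_group = complement_group, psa_sampled = psa_sampled,
             source = source, stringsAsFactors = FALSE)
}

#' @rdname prob_param
#' @param ... One-row data.frames from `prob_param()`.
#' @export
prob_params <- function(...) {
  rows <- list(...)
  if (!length(rows)) {
    return(prob_param("x", 0)[0, ])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cost components
#'
#' A cost component is a resource-use quantity (a count, minutes, km or
#' ml) times a unit price in EUR, tagged with the location where it is
#' incurred, the bearer (healthcare sector or patient -- the societal
#' perspective counts both, the healthcare perspective only the former),
#' and the alternative(s) it applies to. The optional `cost_low`/
#' `cost_high` range is a DSA range on the per-visit component cost in
#' EUR (quantity ranges stated in native units are converted by the unit
#' price when the component is declared).
#'
#' @param id Identifier.
#' @param label Human-readable label used in reports.
#' @param location `"GP"`, `"private_gynaecologist"` or `"hospital"`.
#' @param bearer `"healthcare"` or `"patient"`.
#' @param quantity Resource use per visit; `>= 0`.
#' @param unit_price EUR per unit; `>= 0`.
#' @param applies_to `"both"`, `"usual_practice"` or `"intervention"`.
#' @param cost_low,cost_high Optional DSA range on the per-visit cost
#'   (EUR); `NA` if the component is not varied on its own.
#' @return `cost_component()` returns a one-row data.frame;
#'   `cost_components()` binds its `...` arguments into the costbook of a
#'   [cma_model()].
#' @export
cost_component <- function(id, label, location, bearer, quantity, unit_price,
                           applies_to = "both", cost_low = NA_real_,
                           cost_high = NA_real_) {
  data.frame(id = id, label = label, location = location, bearer = bearer,
             quantity = quantity, unit_price = unit_price,
             applies_to = applies_to, cost_low = cost_low,
             cost_high = cost_high, stringsAsFactors = FALSE)
}

#' @rdname cost_component
#' @param ... One-row data.frames from `cost_component()`.
#' @export
cost_components <- function(...) {
  rows <- list(...)
  if (!length(rows)) {
    return(cost_component("x", "", "GP", "healthcare", 0, 0)[0, ])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
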