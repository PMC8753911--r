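#' Annuity factor (equivalent annual cost)
#'
#' Converts a capital outlay into a constant annual charge: the annuity
#' factor is `(1 - (1 + r)^-L) / r` for interest rate `r > 0` and
#' lifespan `L` years, with the continuity limit `L` at `r = 0`
#' (straight-line depreciation).
#'
#' @param annual_rate Interest rate as a fraction per year (`>= 0`).
#' @param lifespan_years Asset lifespan in years (`> 0`).
#' @return Dimensionless annuity factor.
#' @examples
#' annuity_factor(0.04, 7)  # 6.00205...
#' @export
annuity_factor <- function(annual_rate, lifespan_years) {
  if (!is.numeric(annual_rate) || annual_rate < 0) {
    stop("annual_rate must be >= 0", call. = FALSE)
  }
  if (!is.numeric(lifespan_years) || lifespan_years <= 0) {
    stop("lifespan_years must be > 0", call. = FALSE)
  }
  if (annual_rate == 0) return(lifespan_years)
  (1 - (1 + annual_rate)^(-lifespan_years)) / annual_rate
}

#' Annuity specification for a capital item
#'
#' Describes how a purchase price is converted to a cost per use: the
#' capital (optionally scaled by the fraction of the asset's use
#' attributable to this indication) is annuitised over the lifespan at
#' the interest rate, and the annual charge is divided by the number of
#' uses per year.
#'
#' @param capital Purchase price in EUR.
#' @param lifespan_years Lifespan in years (`> 0`).
#' @param annual_rate Interest rate per year (`>= 0`).
#' @param annual_uses Uses (scans) per year (`> 0`).
#' @param use_fraction Fraction of use attributable to the indication,
#'   in `(0, 1]`.
#' @return An `annuity_spec` list.
#' @export
annuity_spec <- function(capital, lifespan_years, annual_rate, annual_uses,
                         use_fraction = 1) {
  stopifnot(capital >= 0, lifespan_years > 0, annual_rate >= 0,
            annual_uses > 0, use_fraction > 0, use_fraction <= 1)
  structure(
    list(capital = capital, lifespan_years = lifespan_years,
         annual_rate = annual_rate, annual_uses = annual_uses,
         use_fraction = use_fraction),
    class = "annuity_spec"
  )
}

#' Per-use cost of a capital item
#'
#' `capital * use_fraction / annuity_factor(rate, lifespan) / annual_uses`.
#'
#' @param spec An [annuity_spec()].
#' @return EUR per use (per scanning).
#' @examples
#' # POCUS training: course price 2008 EUR over 6 course categories and
#' # 4 gynaecology subcategories, 7-year lifespan, 4% interest, 2.4
#' # scans/GP/year -> 5.81 EUR per scan
#' per_use_capital_cost(annuity_spec(2008 / 6 / 4, 7, 0.04, 2.4))
#' @export
per_use_capital_cost <- function(spec) {
  stopifnot(inherits(spec, "annuity_spec"))
  spec$capital * spec$use_fraction /
    annuity_factor(spec$annual_rate, spec$lifespan_years) / spec$annual_uses
}

#' Cost of one visit at a location
#'
#' Sums `quantity * unit_price` over the cost components incurred at the
#' location under the given alternative (components with `applies_to` of
#' `"both"` or the alternative) and perspective (the healthcare
#' perspective keeps only components borne by the healthcare sector).
#'
#' @param model A `cma_model`.
#' @param location `"GP"`, `"private_gynaecologist"` or `"hospital"`.
#' @param alternative Alternative name.
#' @param perspective `"societal"` or `"healthcare"`.
#' @return EUR per visit.
#' @examples
#' m <- build_paper_model()
#' visit_cost(m, "hospital", "usual_practice")            # 212.18
#' visit_cost(m, "GP", "usual_practice", "healthcare")    # 19.02
#' @export
visit_cost <- function(model, location, alternative,
                       perspective = c("societal", "healthcare")) {
  perspective <- match.arg(perspective)
  check_alternative(model, alternative)
  if (!location %in% valid_locations) {
    stop(sprintf("unknown location '%s'; valid locations: %s", location,
                 paste(valid_locations, collapse = ", ")), call. = FALSE)
  }
  costs <- component_costs(model, alternative, perspective)
  sum(costs[model$costbook$id[model$costbook$location == location]])
}

# The six components of the POCUS add-on (the GP remuneration).
remuneration_component_ids <- c(
  "gp_scan_time", "gp_scanner", "gp_training",
  "gp_wet_wipes", "gp_transducer_cover", "gp_gel"
)

#' GP remuneration for performing POCUS
#'
#' Composes the proposed fee covering the GP's add-on cost of performing
#' point-of-care ultrasonography: scanning time, the annuitised scanner
#' and training costs per scan, and the consumables (wet wipes,
#' transducer cover, gel). These are exactly the intervention-only
#' components of the GP visit, so the total equals the add-on applied to
#' the GP consultation in the intervention arm.
#'
#' @param costbook A costbook data.frame (or a `cma_model`, whose
#'   costbook is used).
#' @param strict If `TRUE` (default), error naming any of the six
#'   required components that is missing; if `FALSE`, return the partial
#'   total with `complete = FALSE`.
#' @return A `remuneration` list: `components` (data.frame with `label`
#'   and `cost` in EUR), `total` (EUR), `complete` (logical), `missing`
#'   (character).
#' @examples
#' remuneration(build_paper_model())  # total 31.98 EUR
#' @export
remuneration <- function(costbook, strict = TRUE) {
  if (inherits(costbook, "cma_model")) costbook <- costbook$costbook
  present <- intersect(remuneration_component_ids, costbook$id)
  missing <- setdiff(remuneration_component_ids, costbook$id)
  if (strict && length(missing)) {
    stop("missing remuneration component(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- costbook[match(present, costbook$id), ]
  components <- data.frame(
    id = rows$id, label = rows$label,
    cost = rows$quantity * rows$unit_price,
    stringsAsFactors = FALSE
  )
  structure(
    list(components = components, total = sum(components$cost),
         complete = !length(missing), missing = missing),
    class = "remuneration"
  )
}

#' @export
print.remuneration <- function(x, ...) {
  cat("<remuneration> POCUS add-on per scanning\n")
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  %-45s EUR %7.3f\n", x$components$label[i],
                x$components$cost[i]))
  }
  cat(sprintf("  %-45s EUR %7.2f\n", "Total", x$total))
  if (!x$complete) {
    cat("  [incomplete: missing", paste(x$missing, collapse = ", "), "]\n")
  }
  invisible(x)
}
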