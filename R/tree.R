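#' Node, branch and tree constructors
#'
#' A cost-minimisation decision tree is a rooted tree whose root is the
#' decision node (one named branch per alternative), whose internal nodes
#' are chance nodes (probabilistic branching over referral events), and
#' whose leaves are terminal nodes tagged with the location where clinical
#' management is completed. Costs accrue on branches: the cost of taking a
#' branch is the sum of the referenced cost components, so a referral path
#' accumulates the GP-visit components plus the specialist-visit components
#' it passes through.
#'
#' @param id Short unique node identifier.
#' @param branches List of [branch()] objects.
#' @param location Completion location for a terminal node; one of
#'   `"GP"`, `"private_gynaecologist"`, `"hospital"`.
#' @return A node object (a list with class `cma_node`).
#' @seealso [branch()], [cma_model()]
#' @export
decision_node <- function(id, branches) {
  new_node(id, "decision", branches = branches)
}

#' @rdname decision_node
#' @export
chance_node <- function(id, branches) {
  new_node(id, "chance", branches = branches)
}

#' @rdname decision_node
#' @export
terminal_node <- function(id, location) {
  new_node(id, "terminal", location = location)
}

new_node <- function(id, kind, branches = list(), location = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  structure(
    list(id = id, kind = kind, branches = branches, location = location),
    class = "cma_node"
  )
}

#' Branch of a decision or chance node
#'
#' @param child Identifier of the child node.
#' @param prob Identifier of the probability parameter attached to the
#'   branch (`NULL` for branches of the decision node).
#' @param costs Character vector of cost-component identifiers accrued
#'   when the branch is taken.
#' @param alternative For root branches only: the alternative's name
#'   (e.g. `"usual_practice"`).
#' @return A branch object (a list with class `cma_branch`).
#' @export
branch <- function(child, prob = NULL, costs = character(), alternative = NULL) {
  structure(
    list(child = child, prob = prob, costs = costs, alternative = alternative),
    class = "cma_branch"
  )
}

#' Assemble a cost-minimisation model
#'
#' Bundles the decision tree with its probability parameters, cost
#' components, cost groups (bundles varied as one sensitivity parameter),
#' annuity specifications and run settings. By default the bundle is
#' validated on construction; see [validate_model()] for the individual
#' invariants.
#'
#' @param tree A list of nodes as returned by the node constructors; the
#'   root must be a decision node.
#' @param params Probability-parameter table, see [prob_params()].
#' @param costbook Cost-component table, see [cost_components()].
#' @param cost_groups Named list; each element is a list with fields
#'   `components` (character vector of component ids) and `low`, `high`
#'   (a range in EUR on the summed per-visit cost of the bundle).
#' @param annuities Named list of [annuity_spec()] objects (documentation
#'   of how annuitised per-scan prices were derived; not used in
#'   evaluation).
#' @param settings List of run settings (`perspective`, `n_draws`,
#'   `seed`).
#' @param root Identifier of the root node (default `"root"`).
#' @param check If `TRUE` (default) stop when [validate_model()] reports
#'   violations.
#' @return An object of class `cma_model`.
#' @export
cma_model <- function(tree, params, costbook, cost_groups = list(),
                      annuities = list(), settings = list(), root = "root",
                      check = TRUE) {
  nodes <- tree
  if (inherits(nodes, "cma_node")) nodes <- list(nodes)
  names(nodes) <- vapply(nodes, `[[`, "", "id")
  model <- structure(
    list(
      root = root,
      nodes = nodes,
      params = params,
      costbook = costbook,
      cost_groups = cost_groups,
      annuities = annuities,
      settings = settings
    ),
    class = "cma_model"
  )
  if (check) {
    bad <- validate_model(model)
    if (length(bad)) {
      stop("invalid model:\n  ", paste(bad, collapse = "\n  "), call. = FALSE)
    }
  }
  model
}

#' @export
print.cma_model <- function(x, ...) {
  alts <- alternatives(x)
  cat("<cma_model>\n")
  cat("  alternatives:", paste(alts, collapse = ", "), "\n")
  cat("  nodes:", length(x$nodes),
      sprintf("(%d chance, %d terminal)\n",
              sum(vapply(x$nodes, function(n) n$kind == "chance", TRUE)),
              sum(vapply(x$nodes, function(n) n$kind == "terminal", TRUE))))
  cat("  probability parameters:", nrow(x$params), "\n")
  cat("  cost components:", nrow(x$costbook), "\n")
  invisible(x)
}

#' Names of the model's alternatives, in declaration order
#'
#' @param model A `cma_model`.
#' @return Character vector of root-branch names.
#' @export
alternatives <- function(model) {
  vapply(model$nodes[[model$root]]$branches, `[[`, "", "alternative")
}

valid_locations <- c("GP", "private_gynaecologist", "hospital")

#' Validate a model against the decision-tree invariants
#'
#' Checks that the graph is a rooted tree (acyclic, single parent, all
#' nodes reachable), that every leaf is a terminal node with a known
#' completion location, that every probability and cost reference
#' resolves, that chance-node branch probabilities sum to 1 (within
#' 1e-9), and that the parameter and cost tables satisfy their own
#' invariants (probabilities and ranges inside `[0, 1]`, complement
#' groups of size two summing to 1, non-negative quantities and unit
#' prices).
#'
#' @param model A `cma_model` (construct with `check = FALSE` to inspect
#'   a deliberately broken model).
#' @return Character vector of human-readable violations; empty when the
#'   model is valid. Violations are returned, never raised.
#' @export
validate_model <- function(model) {
  bad <- character()
  nodes <- model$nodes
  params <- model$params
  costbook <- model$costbook

  if (!model$root %in% names(nodes)) {
    return(sprintf("root node '%s' is not in the node set", model$root))
  }
  root <- nodes[[model$root]]
  if (root$kind != "decision") {
    bad <- c(bad, sprintf("root node '%s' must be a decision node", root$id))
  }
  alts <- vapply(root$branches, function(b) {
    if (is.null(b$alternative)) NA_character_ else b$alternative
  }, "")
  if (anyNA(alts) || !length(alts)) {
    bad <- c(bad, "every root branch must name an alternative")
  }
  if (anyDuplicated(alts)) {
    bad <- c(bad, "alternative names must be unique")
  }
  need_alts <- setdiff(c("usual_practice", "intervention"), alts)
  if (length(need_alts)) {
    bad <- c(bad, sprintf("missing required alternative(s): %s",
                          paste(need_alts, collapse = ", ")))
  }

  ids <- names(nodes)
  if (anyDuplicated(ids)) {
    bad <- c(bad, sprintf("duplicate node id(s): %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }

  # parent structure and reference resolution
  parents <- stats::setNames(rep(0L, length(nodes)), ids)
  for (nd in nodes) {
    if (nd$kind == "terminal") {
      if (length(nd$branches)) {
        bad <- c(bad, sprintf("terminal node '%s' has branches", nd$id))
      }
      if (is.null(nd$location) || !nd$location %in% valid_locations) {
        bad <- c(bad, sprintf(
          "terminal node '%s' needs a completion location in {%s}",
          nd$id, paste(valid_locations, collapse = ", ")))
      }
      next
    }
    if (!length(nd$branches)) {
      bad <- c(bad, sprintf("%s node '%s' has no branches", nd$kind, nd$id))
    }
    for (b in nd$branches) {
      if (!b$child %in% ids) {
        bad <- c(bad, sprintf("node '%s' branches to unknown node '%s'",
                              nd$id, b$child))
      } else {
        parents[b$child] <- parents[b$child] + 1L
      }
      for (cid in b$costs) {
        if (!cid %in% costbook$id) {
          bad <- c(bad, sprintf(
            "branch %s -> %s references missing cost component '%s'",
            nd$id, b$child, cid))
        }
      }
      if (nd$kind == "chance") {
        if (is.null(b$prob)) {
          bad <- c(bad, sprintf(
            "chance-node branch %s -> %s has no probability parameter",
            nd$id, b$child))
        } else if (!b$prob %in% params$id) {
          bad <- c(bad, sprintf(
            "branch %s -> %s references missing probability parameter '%s'",
            nd$id, b$child, b$prob))
        }
      }
    }
    if (nd$kind == "chance") {
      prefs <- vapply(nd$branches, function(b) {
        if (is.null(b$prob)) NA_character_ else b$prob
      }, "")
      known <- prefs[!is.na(prefs) & prefs %in% params$id]
      if (length(known) == length(nd$branches)) {
        s <- sum(params$base[match(known, params$id)])
        if (abs(s - 1) > 1e-9) {
          bad <- c(bad, sprintf(
            "chance node '%s': branch probabilities sum to %.10g, not 1",
            nd$id, s))
        }
      }
    }
  }
  if (parents[model$root] != 0L) {
    bad <- c(bad, sprintf("root node '%s' must have no parent", model$root))
  }
  multi <- names(parents)[parents > 1L]
  if (length(multi)) {
    bad <- c(bad, sprintf("node(s) with more than one parent: %s",
                          paste(multi, collapse = ", ")))
  }
  orphan <- setdiff(names(parents)[parents == 0L], model$root)
  if (length(orphan)) {
    bad <- c(bad, sprintf("unreachable node(s): %s",
                          paste(orphan, collapse = ", ")))
  }

  # parameter table invariants
  if (anyDuplicated(params$id)) {
    bad <- c(bad, "duplicate probability-parameter id(s)")
  }
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    if (is.na(p$base) || p$base < 0 || p$base > 1) {
      bad <- c(bad, sprintf("parameter '%s': base %s outside [0, 1]",
                            p$id, format(p$base)))
    }
    if (!is.na(p$low) && !is.na(p$high)) {
      if (p$low < 0 || p$high > 1 || p$low > p$high) {
        bad <- c(bad, sprintf("parameter '%s': range [%s, %s] invalid",
                              p$id, format(p$low), format(p$high)))
      } else if (p$base < p$low - 1e-12 || p$base > p$high + 1e-12) {
        bad <- c(bad, sprintf("parameter '%s': base outside its range", p$id))
      }
    }
  }
  grp <- split(params, params$complement_group)
  for (gname in setdiff(names(grp), NA)) {
    g <- grp[[gname]]
    if (is.na(gname)) next
    if (nrow(g) != 2L) {
      bad <- c(bad, sprintf(
        "complement group '%s' must have exactly 2 members, has %d",
        gname, nrow(g)))
    } else if (abs(sum(g$base) - 1) > 1e-9) {
      bad <- c(bad, sprintf(
        "complement group '%s': bases sum to %.10g, not 1", gname,
        sum(g$base)))
    }
  }

  # costbook invariants
  if (anyDuplicated(costbook$id)) {
    bad <- c(bad, "duplicate cost-component id(s)")
  }
  for (i in seq_len(nrow(costbook))) {
    cc <- costbook[i, ]
    if (is.na(cc$quantity) || cc$quantity < 0) {
      bad <- c(bad, sprintf("cost component '%s': quantity must be >= 0", cc$id))
    }
    if (is.na(cc$unit_price) || cc$unit_price < 0) {
      bad <- c(bad, sprintf("cost component '%s': unit price must be >= 0", cc$id))
    }
    if (!cc$location %in% valid_locations) {
      bad <- c(bad, sprintf("cost component '%s': unknown location '%s'",
                            cc$id, cc$location))
    }
    if (!cc$bearer %in% c("healthcare", "patient")) {
      bad <- c(bad, sprintf("cost component '%s': unknown bearer '%s'",
                            cc$id, cc$bearer))
    }
    if (!cc$applies_to %in% c("both", alts)) {
      bad <- c(bad, sprintf("cost component '%s': applies_to '%s' matches no alternative",
                            cc$id, cc$applies_to))
    }
  }
  for (gname in names(model$cost_groups)) {
    g <- model$cost_groups[[gname]]
    missing <- setdiff(g$components, costbook$id)
    if (length(missing)) {
      bad <- c(bad, sprintf("cost group '%s' references missing component(s): %s",
                            gname, paste(missing, collapse = ", ")))
    }
  }
  bad
}

# Per-component accrued cost (EUR per visit) under an alternative and
# perspective. `cost_overrides` replaces the per-visit cost of a component
# BEFORE the applies_to/bearer filter, so an override of a component that
# does not apply still contributes nothing.
component_costs <- function(model, alternative, perspective,
                            cost_overrides = NULL) {
  cb <- model$costbook
  cost <- cb$quantity * cb$unit_price
  names(cost) <- cb$id
  if (!is.null(cost_overrides)) {
    unknown <- setdiff(names(cost_overrides), cb$id)
    if (length(unknown)) {
      stop("cost override(s) for unknown component(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cost[names(cost_overrides)] <- cost_overrides
  }
  keep <- (cb$applies_to == "both" | cb$applies_to == alternative)
  if (perspective == "healthcare") keep <- keep & cb$bearer == "healthcare"
  cost[!keep] <- 0
  cost
}

base_probs <- function(model, prob_overrides = NULL) {
  p <- stats::setNames(model$params$base, model$params$id)
  if (!is.null(prob_overrides)) {
    unknown <- setdiff(names(prob_overrides), names(p))
    if (length(unknown)) {
      stop("probability override(s) for unknown parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    p[names(prob_overrides)] <- prob_overrides
  }
  p
}

check_alternative <- function(model, alternative) {
  alts <- alternatives(model)
  if (!alternative %in% alts) {
    stop(sprintf("unknown alternative '%s'; valid alternatives: %s",
                 alternative, paste(alts, collapse = ", ")), call. = FALSE)
  }
}

root_branch <- function(model, alternative) {
  br <- model$nodes[[model$root]]$branches
  br[[match(alternative, vapply(br, `[[`, "", "alternative"))]]
}

#' Expected per-patient cost of one alternative (roll-back)
#'
#' Rolls the tree back bottom-up: the value of a node is the sum over its
#' child branches of branch probability times (cost accrued on the branch
#' plus the child's value). The returned value is the chosen root branch's
#' accrued cost plus its child's value, at full floating precision;
#' rounding to whole euros is left to reporting.
#'
#' @param model A valid `cma_model`.
#' @param alternative Name of a root branch, e.g. `"usual_practice"`.
#' @param perspective `"societal"` (all bearers) or `"healthcare"`
#'   (healthcare-sector costs only; patient time and transport excluded).
#' @param prob_overrides Optional named numeric vector replacing parameter
#'   base values (used by the sensitivity analyses).
#' @param cost_overrides Optional named numeric vector replacing per-visit
#'   component costs in EUR.
#' @return Expected cost in EUR per patient.
#' @examples
#' m <- build_paper_model()
#' expected_cost(m, "usual_practice")   # 234.68...
#' expected_cost(m, "intervention")     # 125.29...
#' @export
expected_cost <- function(model, alternative,
                          perspective = c("societal", "healthcare"),
                          prob_overrides = NULL, cost_overrides = NULL) {
  perspective <- match.arg(perspective)
  check_alternative(model, alternative)
  probs <- base_probs(model, prob_overrides)
  costs <- component_costs(model, alternative, perspective, cost_overrides)
  rb <- root_branch(model, alternative)
  rollback_value(model, rb, probs, costs)
}

rollback_value <- function(model, br, probs, costs) {
  accrued <- sum(costs[br$costs])
  child <- model$nodes[[br$child]]
  if (child$kind == "terminal") return(accrued)
  accrued + sum(vapply(child$branches, function(b) {
    probs[[b$prob]] * rollback_value(model, b, probs, costs)
  }, 0))
}

#' Enumerate all root-to-terminal paths of one alternative
#'
#' Independent oracle for [expected_cost()]: one row per path, with the
#' path probability (product of branch probabilities) and the path cost
#' (sum of accrued component costs under the perspective). Probabilities
#' sum to 1 and `sum(probability * cost)` equals the roll-back value.
#'
#' @inheritParams expected_cost
#' @return A data.frame with columns `path` (node ids joined by `" > "`),
#'   `terminal_location`, `probability` and `cost`; the node-id vectors
#'   are available in the `path_ids` attribute.
#' @export
enumerate_paths <- function(model, alternative,
                            perspective = c("societal", "healthcare"),
                            prob_overrides = NULL, cost_overrides = NULL) {
  perspective <- match.arg(perspective)
  check_alternative(model, alternative)
  probs <- base_probs(model, prob_overrides)
  costs <- component_costs(model, alternative, perspective, cost_overrides)
  st <- path_structure(model, alternative)
  rows <- lapply(st, function(p) {
    data.frame(
      path = paste(p$nodes, collapse = " > "),
      terminal_location = model$nodes[[p$nodes[length(p$nodes)]]]$location,
      probability = prod(probs[p$prob_params]),
      cost = sum(costs[p$cost_ids]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "path_ids") <- lapply(st, `[[`, "nodes")
  out
}

# Structural path decomposition: for each root-to-terminal path the node
# ids, the probability-parameter ids (with multiplicity) and the cost
# component ids (with multiplicity). Pure structure -- no numbers -- so the
# PSA can reuse it across draws.
path_structure <- function(model, alternative) {
  rb <- root_branch(model, alternative)
  walk <- function(br, nodes, prob_params, cost_ids) {
    nodes <- c(nodes, br$child)
    cost_ids <- c(cost_ids, br$costs)
    if (!is.null(br$prob)) prob_params <- c(prob_params, br$prob)
    child <- model$nodes[[br$child]]
    if (child$kind == "terminal") {
      return(list(list(nodes = nodes, prob_params = prob_params,
                       cost_ids = cost_ids)))
    }
    do.call(c, lapply(child$branches, walk, nodes = nodes,
                      prob_params = prob_params, cost_ids = cost_ids))
  }
  walk(rb, model$root, character(), character())
}

#' Evaluate both alternatives and the incremental cost
#'
#' @inheritParams expected_cost
#' @return An `evaluation_result`: a list with `perspective`,
#'   `expected_cost` (named numeric, one entry per alternative in
#'   declaration order) and `incremental` (intervention minus usual
#'   practice; negative values are savings).
#' @examples
#' evaluate_model(build_paper_model())
#' @export
evaluate_model <- function(model, perspective = c("societal", "healthcare"),
                           prob_overrides = NULL, cost_overrides = NULL) {
  perspective <- match.arg(perspective)
  alts <- alternatives(model)
  ec <- vapply(alts, expected_cost, 0, model = model,
               perspective = perspective, prob_overrides = prob_overrides,
               cost_overrides = cost_overrides)
  structure(
    list(perspective = perspective, expected_cost = ec,
         incremental = unname(ec["intervention"] - ec["usual_practice"])),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> perspective: %s\n", x$perspective))
  for (a in names(x$expected_cost)) {
    cat(sprintf("  %-20s EUR %8.2f  (EUR %d rounded)\n", a,
                x$expected_cost[[a]], round(x$expected_cost[[a]])))
  }
  cat(sprintf("  incremental (intervention - usual practice): EUR %.2f\n",
              x$incremental))
  if (x$incremental < 0) {
    cat(sprintf("  => cost-saving of EUR %d per patient (rounded difference)\n",
                round(x$expected_cost[["usual_practice"]]) -
                  round(x$expected_cost[["intervention"]])))
  }
  invisible(x)
}

#' Incremental cost of an evaluation
#'
#' @param result An `evaluation_result` from [evaluate_model()].
#' @return Intervention expected cost minus usual-practice expected cost,
#'   in EUR (negative = cost-saving).
#' @export
incremental_cost <- function(result) {
  ec <- result$expected_cost
  need <- c("usual_practice", "intervention")
  missing <- setdiff(need, names(ec))
  if (length(missing)) {
    stop("evaluation result is missing alternative(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unname(ec[["intervention"]] - ec[["usual_practice"]])
}
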