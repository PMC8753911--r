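# YAML is the one configuration dialect the reader accepts. The schema
# mirrors the model bundle: settings, parameters, costs, cost_groups,
# annuities, tree. Unknown keys are rejected with their location so a
# typo never silently drops an input.

config_schema <- list(
  top = c("settings", "parameters", "costs", "cost_groups", "annuities",
          "tree"),
  settings = c("perspective", "n_draws", "seed"),
  parameter = c("id", "base", "range", "complement_group", "psa_sampled",
                "source"),
  cost = c("id", "label", "location", "bearer", "quantity", "unit_price",
           "applies_to", "range"),
  cost_group = c("id", "components", "range"),
  annuity = c("id", "capital", "lifespan_years", "annual_rate",
              "annual_uses", "use_fraction"),
  tree = c("root", "nodes"),
  node = c("id", "kind", "location", "branches"),
  branch = c("child", "alternative", "prob", "costs")
)

schema_error <- function(where, msg) {
  stop(structure(
    class = c("pocuscma_schema_error", "error", "condition"),
    list(message = sprintf("config %s: %s", where, msg), call = NULL)
  ))
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    schema_error(where, paste("unknown key(s):",
                              paste(unknown, collapse = ", ")))
  }
}

need_key <- function(x, keys, where) {
  missing <- setdiff(keys, names(x))
  if (length(missing)) {
    schema_error(where, paste("missing required key(s):",
                              paste(missing, collapse = ", ")))
  }
}

as_range <- function(x, where) {
  if (is.null(x)) return(c(NA_real_, NA_real_))
  if (!is.numeric(x) || length(x) != 2L) {
    schema_error(where, "range must be a numeric [low, high] pair")
  }
  as.numeric(x)
}

#' Read a model from a YAML configuration file
#'
#' Parses and schema-validates a declarative model description
#' (parameters, cost components, cost groups, annuity specifications and
#' the tree). Schema problems (unknown or missing keys, malformed
#' ranges) are raised as `pocuscma_schema_error`; a structurally sound
#' config whose model breaks a decision-tree invariant (probabilities
#' outside `[0, 1]`, chance nodes not summing to 1, dangling references,
#' a missing standard alternative) is raised as
#' `pocuscma_validation_error` listing every violation.
#'
#' @param path Path to a YAML file; [write_config()] emits the format,
#'   and the bundled case study serves as the reference document
#'   (`write_config(build_paper_model(), "model.yaml")`).
#' @return A validated `cma_model`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    schema_error(path, paste("malformed YAML:", conditionMessage(e)))
  })
  if (!is.list(raw)) schema_error(path, "top level must be a mapping")
  check_keys(raw, config_schema$top, "top level")
  need_key(raw, c("parameters", "costs", "tree"), "top level")

  settings <- raw$settings
  if (!is.null(settings)) check_keys(settings, config_schema$settings, "settings")

  params <- do.call(prob_params, lapply(seq_along(raw$parameters), function(i) {
    p <- raw$parameters[[i]]
    where <- sprintf("parameters[%d]", i)
    check_keys(p, config_schema$parameter, where)
    need_key(p, c("id", "base"), where)
    r <- as_range(p$range, where)
    prob_param(p$id, p$base, r[1], r[2],
               complement_group = p$complement_group %||% NA_character_,
               psa_sampled = isTRUE(p$psa_sampled),
               source = p$source %||% "")
  }))

  costbook <- do.call(cost_components, lapply(seq_along(raw$costs), function(i) {
    cc <- raw$costs[[i]]
    where <- sprintf("costs[%d] ('%s')", i, cc$id %||% "?")
    check_keys(cc, config_schema$cost, where)
    need_key(cc, c("id", "location", "bearer", "quantity", "unit_price"),
             where)
    r <- as_range(cc$range, where)
    cost_component(cc$id, cc$label %||% cc$id, cc$location, cc$bearer,
                   cc$quantity, cc$unit_price,
                   applies_to = cc$applies_to %||% "both",
                   cost_low = r[1], cost_high = r[2])
  }))

  cost_groups <- list()
  for (i in seq_along(raw$cost_groups)) {
    g <- raw$cost_groups[[i]]
    where <- sprintf("cost_groups[%d]", i)
    check_keys(g, config_schema$cost_group, where)
    need_key(g, c("id", "components", "range"), where)
    r <- as_range(g$range, where)
    cost_groups[[g$id]] <- list(components = unlist(g$components),
                                low = r[1], high = r[2])
  }

  annuities <- list()
  for (i in seq_along(raw$annuities)) {
    a <- raw$annuities[[i]]
    where <- sprintf("annuities[%d]", i)
    check_keys(a, config_schema$annuity, where)
    need_key(a, c("id", "capital", "lifespan_years", "annual_rate",
                  "annual_uses"), where)
    annuities[[a$id]] <- annuity_spec(a$capital, a$lifespan_years,
                                      a$annual_rate, a$annual_uses,
                                      a$use_fraction %||% 1)
  }

  tr <- raw$tree
  check_keys(tr, config_schema$tree, "tree")
  need_key(tr, "nodes", "tree")
  nodes <- lapply(seq_along(tr$nodes), function(i) {
    nd <- tr$nodes[[i]]
    where <- sprintf("tree$nodes[%d] ('%s')", i, nd$id %||% "?")
    check_keys(nd, config_schema$node, where)
    need_key(nd, c("id", "kind"), where)
    if (!nd$kind %in% c("decision", "chance", "terminal")) {
      schema_error(where, sprintf("unknown node kind '%s'", nd$kind))
    }
    branches <- lapply(seq_along(nd$branches), function(j) {
      b <- nd$branches[[j]]
      bwhere <- sprintf("%s branch[%d]", where, j)
      check_keys(b, config_schema$branch, bwhere)
      need_key(b, "child", bwhere)
      branch(b$child, prob = b$prob, costs = as.character(unlist(b$costs)),
             alternative = b$alternative)
    })
    new_node(nd$id, nd$kind, branches = branches, location = nd$location)
  })

  model <- cma_model(nodes, params, costbook, cost_groups = cost_groups,
                     annuities = annuities,
                     settings = settings %||% list(),
                     root = tr$root %||% "root", check = FALSE)
  bad <- validate_model(model)
  if (length(bad)) {
    stop(structure(
      class = c("pocuscma_validation_error", "error", "condition"),
      list(message = paste0("config model is invalid:\n  ",
                            paste(bad, collapse = "\n  ")), call = NULL)
    ))
  }
  model
}

#' Write a model to a YAML configuration file
#'
#' Emits the declarative form accepted by [read_config()]; the
#' round-trip `read_config(write_config(model, path))` reproduces a
#' structurally equal model.
#'
#' @param model A `cma_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(model, path) {
  strip_na <- function(x) x[!vapply(x, function(v) all(is.na(v)), TRUE)]
  params <- lapply(seq_len(nrow(model$params)), function(i) {
    p <- model$params[i, ]
    strip_na(list(
      id = p$id, base = p$base,
      range = if (!is.na(p$low)) c(p$low, p$high) else NA,
      complement_group = p$complement_group,
      psa_sampled = p$psa_sampled, source = p$source
    ))
  })
  costs <- lapply(seq_len(nrow(model$costbook)), function(i) {
    cc <- model$costbook[i, ]
    strip_na(list(
      id = cc$id, label = cc$label, location = cc$location,
      bearer = cc$bearer, quantity = cc$quantity,
      unit_price = cc$unit_price, applies_to = cc$applies_to,
      range = if (!is.na(cc$cost_low)) c(cc$cost_low, cc$cost_high) else NA
    ))
  })
  groups <- lapply(names(model$cost_groups), function(g) {
    spec <- model$cost_groups[[g]]
    list(id = g, components = spec$components,
         range = c(spec$low, spec$high))
  })
  annuities <- lapply(names(model$annuities), function(a) {
    s <- model$annuities[[a]]
    list(id = a, capital = s$capital, lifespan_years = s$lifespan_years,
         annual_rate = s$annual_rate, annual_uses = s$annual_uses,
         use_fraction = s$use_fraction)
  })
  nodes <- lapply(model$nodes, function(nd) {
    out <- list(id = nd$id, kind = nd$kind)
    if (!is.null(nd$location)) out$location <- nd$location
    if (length(nd$branches)) {
      out$branches <- lapply(nd$branches, function(b) {
        bb <- list(child = b$child)
        if (!is.null(b$alternative)) bb$alternative <- b$alternative
        if (!is.null(b$prob)) bb$prob <- b$prob
        if (length(b$costs)) bb$costs <- as.list(b$costs)
        bb
      })
    }
    out
  })
  doc <- list(
    settings = model$settings,
    parameters = params,
    costs = costs,
    cost_groups = groups,
    annuities = annuities,
    tree = list(root = model$root, nodes = unname(nodes))
  )
  doc <- doc[vapply(doc, length, 0L) > 0]
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
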