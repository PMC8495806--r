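# Data model and topology operations for trophic networks.
#
# A food web is a list of trophic compartments ("nodes": species or functional
# feeding guilds) plus directed feeding links (resource -> consumer). Node
# order is always the input order; all matrices derived from a web use the
# convention resources in rows, consumers in columns.

#' Default unit tags for a food web
#'
#' Units are opaque coherent tags: the package never converts them, it only
#' checks that they are declared and refuses to combine webs whose tags
#' differ. Defaults describe fresh-mass densities in mg per square metre and
#' energy in Joules per hour.
#'
#' @return Named list with elements `mass`, `area`, `energy`, `time`.
#' @export
default_units <- function() {
  list(mass = "mg", area = "m2", energy = "J", time = "h")
}

node_columns <- c("node_id", "name", "guild", "resource_type", "biomass",
                  "abundance", "mean_body_mass", "loss", "is_basal")

#' Assemble and validate a food web
#'
#' Builds a `food_web` object from a node table and a link table. Basal
#' status (a node with no resources of its own) is always derived from the
#' link structure; if the node table carries an `is_basal` column it must
#' agree with the derived flags.
#'
#' @param node_records Data frame with at least `node_id` (unique) and
#'   `biomass` (fresh-mass density per unit area, >= 0). Optional columns:
#'   `name`, `guild`, `resource_type` (one of `"animal"`, `"plant"`,
#'   `"detritus"`; used when the node is eaten), `abundance` (individuals per
#'   unit area), `mean_body_mass`, `loss` (metabolic demand X), `is_basal`.
#' @param link_records Data frame with `resource_id`, `consumer_id` and an
#'   optional `active_weight` column (>= 0). A missing weight defaults to 1
#'   except on cannibalistic self-links, which require an explicit weight so
#'   that biomass-driven (passive) preferences cannot silently inflate
#'   self-consumption.
#' @param losses_per_unit_biomass Logical; `TRUE` when each node's `loss` is
#'   expressed per unit biomass (it is multiplied by the node biomass before
#'   solving), `FALSE` when losses are whole-node totals.
#' @param temperature_C Ambient temperature in degrees Celsius.
#' @param units Named list of unit tags, see [default_units()].
#' @param body_masses Optional named list: `node_id` -> numeric vector of
#'   individual fresh body masses (> 0).
#' @return An object of class `food_web`: a list with elements `nodes`
#'   (data frame), `links` (data frame), `body_masses` (named list),
#'   `losses_per_unit_biomass`, `temperature_C`, `units`.
#' @examples
#' nodes <- data.frame(node_id = c("plant", "herb", "pred"),
#'                     resource_type = c("plant", "animal", "animal"),
#'                     biomass = c(1000, 100, 10),
#'                     loss = c(NA, 2, 1))
#' links <- data.frame(resource_id = c("plant", "herb"),
#'                     consumer_id = c("herb", "pred"))
#' build_web(nodes, links, losses_per_unit_biomass = FALSE)
#' @export
build_web <- function(node_records, link_records,
                      losses_per_unit_biomass = TRUE,
                      temperature_C = 20,
                      units = default_units(),
                      body_masses = NULL) {
  stopifnot(is.data.frame(node_records))
  if (!"node_id" %in% names(node_records)) stop("node table needs a node_id column")
  if (!"biomass" %in% names(node_records)) stop("node table needs a biomass column")
  nodes <- node_records
  nodes$node_id <- as.character(nodes$node_id)

  dup <- nodes$node_id[duplicated(nodes$node_id)]
  if (length(dup)) stop("duplicate node_id: ", paste(unique(dup), collapse = ", "))

  links <- if (is.null(link_records) || nrow(as.data.frame(link_records)) == 0) {
    data.frame(resource_id = character(), consumer_id = character(),
               active_weight = numeric())
  } else {
    as.data.frame(link_records)
  }
  if (nrow(links)) {
    if (!all(c("resource_id", "consumer_id") %in% names(links)))
      stop("link table needs resource_id and consumer_id columns")
    links$resource_id <- as.character(links$resource_id)
    links$consumer_id <- as.character(links$consumer_id)
    if (!"active_weight" %in% names(links)) links$active_weight <- NA_real_
    links$active_weight <- as.numeric(links$active_weight)

    dangling <- setdiff(c(links$resource_id, links$consumer_id), nodes$node_id)
    if (length(dangling))
      stop("link endpoint not in node table: ", paste(dangling, collapse = ", "))

    self <- links$resource_id == links$consumer_id
    if (any(self & is.na(links$active_weight)))
      stop("cannibalistic self-link on ",
           paste(links$consumer_id[self & is.na(links$active_weight)], collapse = ", "),
           " requires an explicit active_weight (passive preferences must not",
           " drive self-consumption)")
    links$active_weight[is.na(links$active_weight)] <- 1
    if (any(links$active_weight < 0)) stop("negative active_weight")
    key <- paste(links$resource_id, links$consumer_id)
    if (anyDuplicated(key)) stop("duplicate link: ", key[duplicated(key)][1])
  }

  # fill optional columns
  for (col in setdiff(node_columns, names(nodes))) {
    nodes[[col]] <- switch(col,
      name = nodes$node_id,
      guild = NA_character_,
      resource_type = NA_character_,
      abundance = NA_real_, mean_body_mass = NA_real_, loss = NA_real_,
      is_basal = NA)
  }
  nodes$biomass <- as.numeric(nodes$biomass)
  if (anyNA(nodes$biomass) || any(nodes$biomass < 0)) stop("negative or missing biomass")
  if (any(!is.na(nodes$abundance) & nodes$abundance < 0)) stop("negative abundance")
  if (any(!is.na(nodes$loss) & nodes$loss < 0)) stop("negative loss")
  rt <- nodes$resource_type
  if (any(!is.na(rt) & !rt %in% c("animal", "plant", "detritus")))
    stop("resource_type must be one of animal/plant/detritus")

  derived_basal <- !(nodes$node_id %in% links$consumer_id)
  if (!all(is.na(nodes$is_basal))) {
    user <- as.logical(nodes$is_basal)
    bad <- which(!is.na(user) & user != derived_basal)
    if (length(bad))
      stop("user is_basal flag contradicts topology for: ",
           paste(nodes$node_id[bad], collapse = ", "))
  }
  nodes$is_basal <- derived_basal
  if (!any(nodes$is_basal)) stop("no basal node (every node has resources)")
  if (all(nodes$is_basal)) stop("no consumer node")

  if (is.null(body_masses)) body_masses <- list()
  if (length(body_masses)) {
    bad <- setdiff(names(body_masses), nodes$node_id)
    if (length(bad)) stop("body masses for unknown node: ", paste(bad, collapse = ", "))
    if (any(vapply(body_masses, function(m) length(m) < 1 || any(m <= 0), TRUE)))
      stop("every body mass must be > 0 and each list non-empty")
  }

  nodes <- nodes[, node_columns]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, links = links, body_masses = body_masses,
                 losses_per_unit_biomass = isTRUE(losses_per_unit_biomass),
                 temperature_C = as.numeric(temperature_C),
                 units = units),
            class = "food_web")
}

#' @export
print.food_web <- function(x, ...) {
  cat(sprintf("food_web: %d nodes, %d links, %d basal; T = %g degC; losses %s\n",
              nrow(x$nodes), nrow(x$links), sum(x$nodes$is_basal),
              x$temperature_C,
              if (x$losses_per_unit_biomass) "per unit biomass" else "per node"))
  cat("units:", paste(names(x$units), unlist(x$units), sep = "=", collapse = " "), "\n")
  invisible(x)
}

n_nodes <- function(web) nrow(web$nodes)
node_ids <- function(web) web$nodes$node_id

# consumer -> resource digraph (edges point down the chain)
web_graph_down <- function(web) {
  igraph::graph_from_data_frame(
    data.frame(from = web$links$consumer_id, to = web$links$resource_id),
    directed = TRUE,
    vertices = data.frame(name = node_ids(web)))
}

#' Diagnostic checks on a food web
#'
#' Runs the data-hygiene checks that commonly bite flux calculations:
#' consumers unreachable from any basal node, consumers whose whole diet has
#' zero biomass (a division-by-zero under passive preferences), consumers
#' with neither a metabolic loss nor any body-mass route to one, and missing
#' unit tags.
#'
#' @param web A `food_web`.
#' @param use_biomass Logical; whether biomass-driven (passive) preferences
#'   are intended, which makes a zero-biomass diet an error.
#' @return Data frame with columns `severity` (`"error"`/`"warning"`),
#'   `code`, `node_id`, `message`; zero rows when the web is clean.
#' @export
validate_web <- function(web, use_biomass = TRUE) {
  stopifnot(inherits(web, "food_web"))
  diags <- list()
  add <- function(severity, code, node_id, message)
    diags[[length(diags) + 1]] <<- data.frame(severity = severity, code = code,
                                              node_id = node_id, message = message)

  nodes <- web$nodes
  g_up <- igraph::graph_from_data_frame(
    data.frame(from = web$links$resource_id, to = web$links$consumer_id),
    directed = TRUE, vertices = data.frame(name = node_ids(web)))
  basal <- nodes$node_id[nodes$is_basal]
  reach <- unique(unlist(lapply(basal, function(b)
    names(igraph::subcomponent(g_up, b, mode = "out")))))
  for (id in setdiff(nodes$node_id, reach))
    add("warning", "unreachable", id,
        sprintf("node '%s' is unreachable from any basal node", id))

  consumers <- nodes$node_id[!nodes$is_basal]
  for (c_id in consumers) {
    res <- web$links$resource_id[web$links$consumer_id == c_id]
    if (use_biomass && all(nodes$biomass[match(res, nodes$node_id)] == 0))
      add("error", "zero_biomass_diet", c_id,
          sprintf("consumer '%s': all resources have biomass 0; passive preferences are undefined", c_id))
    i <- match(c_id, nodes$node_id)
    has_loss <- !is.na(nodes$loss[i])
    has_masses <- !is.null(web$body_masses[[c_id]]) ||
      (!is.na(nodes$mean_body_mass[i]) && !is.na(nodes$abundance[i]))
    if (!has_loss && !has_masses)
      add("error", "no_metabolic_route", c_id,
          sprintf("consumer '%s': cannot derive metabolic demand (no loss and no body-mass data)", c_id))
  }

  u <- web$units
  missing_units <- names(default_units())[!vapply(names(default_units()), function(k)
    !is.null(u[[k]]) && !is.na(u[[k]]) && nzchar(u[[k]]), TRUE)]
  if (length(missing_units))
    add("warning", "missing_units", NA_character_,
        paste("missing unit tags:", paste(missing_units, collapse = ", ")))

  if (length(diags)) do.call(rbind, diags) else
    data.frame(severity = character(), code = character(),
               node_id = character(), message = character())
}

#' Top-down ordering of a food web
#'
#' Orders nodes from the highest-level consumers downward so that every
#' consumer precedes all of its resources — the order in which the flux
#' balance can be applied sequentially by hand.
#'
#' @param web A `food_web`.
#' @return A character vector of node ids when the consumer-to-resource
#'   digraph is acyclic; otherwise an object of class `flux_cycle_report`
#'   listing the nodes that sit on cycles.
#' @export
topological_order <- function(web) {
  g <- web_graph_down(web)
  loops <- web$links$consumer_id[web$links$resource_id == web$links$consumer_id]
  comp <- igraph::components(g, mode = "strong")
  on_cycle <- names(comp$membership)[comp$membership %in%
                                       which(tabulate(comp$membership) > 1)]
  on_cycle <- sort(unique(c(on_cycle, loops)))
  if (length(on_cycle))
    return(structure(list(cycle_nodes = on_cycle), class = "flux_cycle_report"))
  ord <- igraph::topo_sort(g, mode = "out")
  names(ord)
}

#' @export
print.flux_cycle_report <- function(x, ...) {
  cat("food web contains trophic cycles through:",
      paste(x$cycle_nodes, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate nodes of a food web into groups
#'
#' Merges nodes according to a partition: biomasses, abundances and (per-node)
#' losses are summed, individual body masses concatenated, links rebuilt as
#' the union of member links with active weights combined as
#' consumer-biomass-weighted means. Merges are classified as *parallel* when
#' every multi-member group's members share identical resource and consumer
#' sets outside the group (safe), and *serial* when some member feeds on
#' another member (a warning is emitted and the would-be intra-group links are
#' dropped).
#'
#' @param web A `food_web`.
#' @param partition Named character vector `node_id -> group_id` covering all
#'   nodes.
#' @return A new `food_web` whose nodes are the groups (ordered by first
#'   appearance). The attribute `"aggregation"` records the classification
#'   and the weight-combination rule.
#' @export
aggregate_nodes <- function(web, partition) {
  stopifnot(inherits(web, "food_web"))
  ids <- node_ids(web)
  if (!all(ids %in% names(partition))) stop("partition must cover all nodes")
  grp <- as.character(partition[ids])
  if (anyNA(grp) || any(!nzchar(grp))) stop("empty group id in partition")
  groups <- unique(grp)

  nodes <- web$nodes
  per_biomass <- web$losses_per_unit_biomass

  new_nodes <- do.call(rbind, lapply(groups, function(g) {
    m <- nodes[grp == g, , drop = FALSE]
    rtypes <- unique(m$resource_type[!is.na(m$resource_type)])
    if (length(rtypes) > 1)
      stop("group '", g, "' mixes resource types: ", paste(rtypes, collapse = ", "))
    if (nrow(m) == 1) {
      out <- m
      out$node_id <- g
      return(out)
    }
    B <- m$biomass
    loss <- if (all(is.na(m$loss))) NA_real_ else if (per_biomass) {
      # per-unit-biomass losses combine as a biomass-weighted mean so that the
      # group's total (loss * biomass) is conserved
      sum(m$loss * B, na.rm = TRUE) / sum(B[!is.na(m$loss)])
    } else sum(m$loss, na.rm = TRUE)
    ab <- if (all(is.na(m$abundance))) NA_real_ else sum(m$abundance, na.rm = TRUE)
    mbm <- if (!is.na(ab) && ab > 0 && !all(is.na(m$mean_body_mass)))
      sum(m$mean_body_mass * m$abundance, na.rm = TRUE) / ab else NA_real_
    data.frame(node_id = g, name = paste(m$name, collapse = "+"),
               guild = paste(unique(m$guild), collapse = "+"),
               resource_type = if (length(rtypes)) rtypes else NA_character_,
               biomass = sum(B), abundance = ab, mean_body_mass = mbm,
               loss = loss, is_basal = NA)
  }))

  links <- web$links
  classification <- "parallel"
  if (nrow(links)) {
    gr <- grp[match(links$resource_id, ids)]
    gc <- grp[match(links$consumer_id, ids)]
    intra <- gr == gc & links$resource_id != links$consumer_id
    if (any(intra)) {
      classification <- "serial"
      warning("serial aggregation: group(s) ",
              paste(unique(gr[intra]), collapse = ", "),
              " merge nodes that feed on each other; intra-group links dropped",
              call. = FALSE)
    }
    keep <- !intra
    if (any(keep)) {
      Bc <- nodes$biomass[match(links$consumer_id, ids)]
      key <- paste(gr, gc, sep = "\r")
      agg_w <- tapply((links$active_weight * Bc)[keep], key[keep], sum) /
        tapply(Bc[keep], key[keep], sum)
      parts <- strsplit(names(agg_w), "\r", fixed = TRUE)
      links <- data.frame(resource_id = vapply(parts, `[`, "", 1),
                          consumer_id = vapply(parts, `[`, "", 2),
                          active_weight = as.numeric(agg_w))
    } else {
      links <- links[0, ]
    }
    # restore deterministic order: by consumer then resource group appearance
    links <- links[order(match(links$consumer_id, groups),
                         match(links$resource_id, groups)), ]
    rownames(links) <- NULL
  }

  if (classification == "parallel") {
    for (g in groups[table(factor(grp, groups)) > 1]) {
      members <- ids[grp == g]
      rsets <- lapply(members, function(m)
        sort(setdiff(web$links$resource_id[web$links$consumer_id == m], members)))
      csets <- lapply(members, function(m)
        sort(setdiff(web$links$consumer_id[web$links$resource_id == m], members)))
      if (length(unique(rsets)) > 1 || length(unique(csets)) > 1) {
        classification <- "mixed"
        break
      }
    }
  }

  bm <- list()
  for (g in groups) {
    v <- unlist(web$body_masses[ids[grp == g]], use.names = FALSE)
    if (length(v)) bm[[g]] <- v
  }

  out <- build_web(new_nodes[, setdiff(node_columns, "is_basal")], links,
                   losses_per_unit_biomass = per_biomass,
                   temperature_C = web$temperature_C,
                   units = web$units, body_masses = bm)
  attr(out, "aggregation") <- list(classification = classification,
                                   weight_rule = "consumer-biomass-weighted mean")
  out
}
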