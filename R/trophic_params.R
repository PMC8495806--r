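# Realized feeding preferences (diet shares) and assimilation efficiencies.

#' Realized feeding-preference matrix
#'
#' Combines active consumer choice weights with passive, encounter-driven
#' preferences (relative resource biomass): `W[r, c] = w_rc * B_r /
#' sum_r'(w_r'c * B_r')` when `use_biomass = TRUE`, or the active weights
#' alone normalized per consumer otherwise (equal weights then reduce to the
#' uniform null assumption). Matrix orientation is resources in rows,
#' consumers in columns, node order as in the web.
#'
#' @param web A `food_web`.
#' @param use_biomass Logical; scale active weights by resource biomass
#'   (passive preferences).
#' @return Numeric matrix `W` with each consumer column summing to 1, zero
#'   entries exactly where no link exists, and all-zero basal columns.
#'   Attribute `"mode"` records `"combined"` or `"active-only"`.
#' @export
compute_preferences <- function(web, use_biomass = TRUE) {
  stopifnot(inherits(web, "food_web"))
  ids <- node_ids(web)
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  links <- web$links
  w <- links$active_weight
  if (use_biomass)
    w <- w * web$nodes$biomass[match(links$resource_id, ids)]
  W[cbind(match(links$resource_id, ids), match(links$consumer_id, ids))] <- w
  for (j in which(!web$nodes$is_basal)) {
    s <- sum(W[, j])
    if (s == 0)
      stop("consumer '", ids[j], "': preference normalization denominator is 0",
           if (use_biomass) " (all resources have zero biomass * weight)" else "")
    W[, j] <- W[, j] / s
  }
  attr(W, "mode") <- if (use_biomass) "combined" else "active-only"
  W
}

#' Bundled default assimilation efficiencies
#'
#' Literature-derived averages for terrestrial arthropod food webs at a
#' reference temperature of 20 degrees Celsius: 0.158 for detritus, 0.545 for
#' plant (autotroph) and 0.906 for animal (heterotroph) resources (Lang et
#' al. 2017).
#'
#' @param path Optional path to a user table with columns
#'   `resource_type, e, reference_temperature_C, source`.
#' @return Data frame with those columns.
#' @export
default_efficiencies <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "assimilation_efficiencies.csv",
                        package = "trophicflux", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Assign assimilation efficiencies to the nodes of a web
#'
#' At resource level (the default, and the convention preferred in trophic
#' ecology) every node that can be eaten receives the efficiency of its
#' resource type: consumers of mixed diets then lose more of a detritus meal
#' than of an animal meal. At consumer level each consumer receives one
#' efficiency keyed by its guild. An optional temperature hook
#' `function(e, delta_T)` maps the tabulated efficiency and the offset from
#' the table's reference temperature to an adjusted value (clamped to (0, 1]);
#' the default is the identity, i.e. constant efficiencies — no
#' temperature-dependence formula is invented here.
#'
#' @param web A `food_web`.
#' @param table Data frame as returned by [default_efficiencies()] (resource
#'   level: keyed by `resource_type`; consumer level: keyed by a `guild`
#'   column), or a named numeric vector of efficiencies with an attached
#'   `reference_temperature_C` of 20 assumed.
#' @param temperature_C Ambient temperature (defaults to the web's).
#' @param level `"resource"` or `"consumer"`.
#' @param hook Optional `function(e, delta_T)` temperature adjustment.
#' @return An `efficiency_assignment`: list with `level`, `e` (named per-node
#'   vector in (0, 1], `NA` for nodes the level does not cover),
#'   `reference_temperature_C`, `source`.
#' @export
assign_efficiencies <- function(web, table = default_efficiencies(),
                                temperature_C = web$temperature_C,
                                level = c("resource", "consumer"),
                                hook = NULL) {
  stopifnot(inherits(web, "food_web"))
  level <- match.arg(level)
  if (is.numeric(table)) {
    ref <- attr(table, "reference_temperature_C")
    table <- data.frame(key = names(table), e = as.numeric(table),
                        reference_temperature_C = if (is.null(ref)) 20 else ref,
                        source = "user")
  } else {
    key_col <- if (level == "resource") "resource_type" else "guild"
    if (!key_col %in% names(table))
      stop("efficiency table needs a '", key_col, "' column at ", level, " level")
    table <- data.frame(key = table[[key_col]], e = table$e,
                        reference_temperature_C = table$reference_temperature_C,
                        source = table$source)
  }
  if (any(!is.finite(table$e) | table$e <= 0 | table$e > 1))
    stop("efficiencies must lie in (0, 1]")

  nodes <- web$nodes
  e <- rep(NA_real_, nrow(nodes))
  names(e) <- nodes$node_id
  if (level == "resource") {
    eaten <- nodes$node_id %in% web$links$resource_id
    keys <- nodes$resource_type
    need <- eaten
  } else {
    need <- !nodes$is_basal
    keys <- nodes$guild
  }
  idx <- match(keys, table$key)
  uncovered <- need & is.na(idx)
  if (any(uncovered))
    stop("no efficiency for ", level, "-level key of node(s): ",
         paste(nodes$node_id[uncovered], collapse = ", "))
  fill <- !is.na(idx)
  e[fill] <- table$e[idx[fill]]
  ref_t <- if (any(fill)) table$reference_temperature_C[idx[fill]][1] else 20

  if (!is.null(hook)) {
    adj <- hook(e[fill], temperature_C - ref_t)
    e[fill] <- pmin(pmax(adj, .Machine$double.eps), 1)
  }
  structure(list(level = level, e = e, reference_temperature_C = ref_t,
                 source = paste(unique(table$source[idx[fill]]), collapse = "; ")),
            class = "efficiency_assignment")
}

#' @export
print.efficiency_assignment <- function(x, ...) {
  cat("assimilation efficiencies (", x$level, " level, reference ",
      x$reference_temperature_C, " degC):\n", sep = "")
  print(x$e)
  invisible(x)
}
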