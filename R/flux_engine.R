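# Steady-state flux balance: every consumer's assimilated intake equals its
# own metabolic demand plus its loss to consumption by higher levels,
# F = (X + L) / e_a per link, applied network-wide.
#
# Matrix form (resource-level efficiencies): for every consumer c with total
# consumption G_c,
#     ebar_c * G_c - sum_k W[c, k] * G_k = X_c,   ebar_c = sum_r e_r * W[r, c]
# (consumer-level: e_c replaces ebar_c). Basal nodes have G = 0 — the energy
# flowing *into* basal resources is outside the balance. Link fluxes are
# F[r, c] = W[r, c] * G_c.

node_loss_vector <- function(web, losses = NULL) {
  if (!is.null(losses)) {
    stopifnot(length(losses) == n_nodes(web))
    x <- as.numeric(losses)
  } else {
    x <- web$nodes$loss
    if (web$losses_per_unit_biomass) x <- x * web$nodes$biomass
  }
  x[web$nodes$is_basal & is.na(x)] <- 0
  if (anyNA(x))
    stop("missing loss for consumer(s): ",
         paste(web$nodes$node_id[is.na(x)], collapse = ", "),
         " (run node_losses() first or supply losses)")
  if (any(x < 0)) stop("negative loss")
  names(x) <- node_ids(web)
  x
}

effective_e <- function(W, eff) {
  if (eff$level == "resource") as.numeric(crossprod(W, ifelse(is.na(eff$e), 0, eff$e)))
  else as.numeric(eff$e)
}

finish_solution <- function(web, W, G, X, eff, method) {
  n <- length(G)
  F <- sweep(W, 2, G, `*`)
  sol <- structure(list(F = F, G = G, L = rowSums(F), X = X,
                        eff = eff, units = web$units, method = method,
                        residuals = NULL),
                   class = "flux_solution")
  sol$residuals <- balance_residuals(sol, web)
  sol
}

#' Solve all link fluxes of a food web (linear-system solver)
#'
#' Solves the steady-state energy balance for every consumer simultaneously
#' as one linear system, so omnivory and trophic loops (mutual predation,
#' actively down-weighted cannibalism) are handled. The result is the
#' *minimum* flux consistent with every organism staying alive at its
#' metabolic demand.
#'
#' @param web A `food_web`.
#' @param W Preference matrix from [compute_preferences()]; computed with
#'   biomass scaling by default.
#' @param losses Per-node loss vector X (whole-node basis, web node order).
#'   Defaults to the web's loss column (multiplied by biomass when the web
#'   declares per-unit-biomass losses).
#' @param eff An [assign_efficiencies()] result.
#' @return A `flux_solution`: list with `F` (link-flux matrix, resources in
#'   rows, consumers in columns), `G` (per-consumer total consumption),
#'   `L` (per-node loss to consumption), `X`, `residuals` (per-consumer
#'   relative balance errors), `units`, `method`.
#' @export
solve_fluxes <- function(web, W = compute_preferences(web),
                         losses = NULL, eff = assign_efficiencies(web)) {
  stopifnot(inherits(web, "food_web"))
  X <- node_loss_vector(web, losses)
  ids <- node_ids(web)
  cons <- which(!web$nodes$is_basal)
  ebar <- effective_e(W, eff)
  if (any(!is.finite(ebar[cons]) | ebar[cons] <= 0))
    stop("non-positive effective efficiency for consumer(s): ",
         paste(ids[cons][!is.finite(ebar[cons]) | ebar[cons] <= 0], collapse = ", "))
  A <- diag(ebar[cons], nrow = length(cons)) - W[cons, cons, drop = FALSE]
  G <- rep(0, length(ids))
  names(G) <- ids
  sol <- tryCatch(solve(A, X[cons]),
                  error = function(e) stop("singular flux balance: structurally",
                                           " infeasible web (", conditionMessage(e), ")",
                                           call. = FALSE))
  sol[abs(sol) < 1e-14 * max(abs(sol), 1)] <- 0
  if (any(sol < 0))
    stop("energetically infeasible configuration: negative consumption for ",
         paste(ids[cons][sol < 0], collapse = ", "))
  G[cons] <- sol
  finish_solution(web, W, G, X, eff, "matrix")
}

#' Solve link fluxes sequentially from the top of the web
#'
#' Applies the single-link balance `F = (X + L) / e_a` node by node, starting
#' at the highest-level consumers and accumulating each node's loss to
#' consumption on the way down — the by-hand procedure. Only defined on
#' acyclic webs; it serves as an independent oracle for [solve_fluxes()].
#'
#' @inheritParams solve_fluxes
#' @return A `flux_solution` (see [solve_fluxes()]).
#' @export
solve_fluxes_sequential <- function(web, W = compute_preferences(web),
                                    losses = NULL, eff = assign_efficiencies(web)) {
  stopifnot(inherits(web, "food_web"))
  ord <- topological_order(web)
  if (inherits(ord, "flux_cycle_report"))
    stop("web contains trophic cycles (",
         paste(ord$cycle_nodes, collapse = ", "),
         "); use solve_fluxes() for webs with loops")
  X <- node_loss_vector(web, losses)
  ids <- node_ids(web)
  ebar <- effective_e(W, eff)
  G <- rep(0, length(ids))
  names(G) <- ids
  basal <- web$nodes$is_basal
  names(basal) <- ids
  for (id in ord) {
    if (basal[id]) next
    L_id <- sum(W[id, ] * G)  # consumers of id are already solved
    if (ebar[match(id, ids)] <= 0)
      stop("non-positive effective efficiency for consumer '", id, "'")
    G[id] <- (X[id] + L_id) / ebar[match(id, ids)]
    if (G[id] < 0)
      stop("energetically infeasible configuration: negative consumption for ", id)
  }
  finish_solution(web, W, G, X, eff, "sequential")
}

#' Per-consumer balance residuals of a flux solution
#'
#' For each consumer, the relative violation of the steady-state balance:
#' `|assimilated intake - X - loss to consumption| / max(X, eps)`, where the
#' assimilated intake is `sum_r e_r * F[r, c]` under resource-level
#' efficiencies or `e_c * sum_r F[r, c]` under consumer-level ones.
#'
#' @param solution A `flux_solution`.
#' @param web The `food_web` it was solved on.
#' @param W,losses,eff Optional overrides; by default taken from the solution
#'   itself (`W` reconstructed from `F` and `G`).
#' @param eps Floor for the relative scaling (default 1e-12).
#' @return Named numeric vector of residuals over consumers.
#' @export
balance_residuals <- function(solution, web, W = NULL, losses = NULL,
                              eff = NULL, eps = 1e-12) {
  stopifnot(inherits(solution, "flux_solution"))
  F <- solution$F
  X <- if (is.null(losses)) solution$X else node_loss_vector(web, losses)
  eff <- if (is.null(eff)) solution$eff else eff
  cons <- which(!web$nodes$is_basal)
  e <- eff$e
  out <- vapply(cons, function(c) {
    assim <- if (eff$level == "resource")
      sum(ifelse(is.na(e), 0, e) * F[, c]) else e[c] * sum(F[, c])
    abs(assim - X[c] - sum(F[c, ])) / max(X[c], eps)
  }, numeric(1))
  names(out) <- node_ids(web)[cons]
  out
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("flux_solution (%s solver): %d links carry flux; total flux %.6g %s per %s per %s\n",
              x$method, sum(x$F > 0), sum(x$F),
              x$units$energy, x$units$area, x$units$time))
  cat(sprintf("max consumer balance residual: %.3g (relative)\n",
              if (length(x$residuals)) max(x$residuals) else NA))
  invisible(x)
}
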