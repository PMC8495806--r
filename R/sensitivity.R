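# Monte-Carlo sensitivity: how does uncertainty in metabolic losses,
# assimilation efficiencies, or feeding preferences propagate to fluxes?
#
# Each draw multiplies the chosen parameter elementwise by independent
# factors 1 + v*u with u ~ Uniform(-1, 1) (so a fixed seed gives one u-field
# reused across v, and the stress grows monotonically with v). Perturbed
# efficiencies are clamped to (0, 1]; perturbed preference columns are
# re-normalized. The perturbation of preferences is link-wise (then
# re-normalized), not node-wise.

#' Parameter-uncertainty sensitivity of a flux solution
#'
#' @param web A `food_web`.
#' @param parameter `"losses"`, `"efficiencies"`, or `"preferences"`.
#' @param v Perturbation half-width as a fraction (0 <= v < 1): factors are
#'   uniform on `[1 - v, 1 + v]`.
#' @param n Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed; identical seed and inputs reproduce the report
#'   exactly.
#' @param W,losses,eff The unperturbed inputs, defaulting as in
#'   [solve_fluxes()].
#' @param trace Keep the drawn factor matrix in the report (for audit).
#' @return A `sensitivity_report`: the perturbed parameter, `v`, `n`, `seed`,
#'   per-link and per-node data frames of mean relative deviation and
#'   coefficient of variation, counts of infeasible draws and of clamped
#'   efficiency values, and (with `trace`) the factors.
#' @export
perturb_and_recompute <- function(web, parameter = c("losses", "efficiencies",
                                                     "preferences"),
                                  v, n, seed = 1,
                                  W = compute_preferences(web),
                                  losses = NULL,
                                  eff = assign_efficiencies(web),
                                  trace = FALSE) {
  stopifnot(inherits(web, "food_web"))
  parameter <- match.arg(parameter)
  if (!is.finite(v) || v < 0 || v >= 1) stop("v must satisfy 0 <= v < 1")
  if (n < 1) stop("n must be >= 1")
  X <- node_loss_vector(web, losses)
  base <- solve_fluxes(web, W, X, eff)
  ids <- node_ids(web)
  cons <- which(!web$nodes$is_basal)
  link_idx <- cbind(match(web$links$resource_id, ids),
                    match(web$links$consumer_id, ids))

  n_target <- switch(parameter,
                     losses = length(cons),
                     efficiencies = sum(!is.na(eff$e)),
                     preferences = nrow(link_idx))
  u <- withr::with_seed(seed,
                        matrix(stats::runif(n * n_target, -1, 1), nrow = n))

  F_draws <- array(NA_real_, c(n, nrow(link_idx)))
  G_draws <- array(NA_real_, c(n, length(cons)))
  n_infeasible <- 0L
  n_clamped <- 0L
  for (d in seq_len(n)) {
    f <- 1 + v * u[d, ]
    Wd <- W; Xd <- X; effd <- eff
    if (parameter == "losses") {
      Xd[cons] <- X[cons] * f
    } else if (parameter == "efficiencies") {
      e2 <- effd$e
      live <- !is.na(e2)
      e2[live] <- e2[live] * f
      clamped <- live & (e2 > 1 | e2 <= 0)
      n_clamped <- n_clamped + sum(clamped)
      e2[live] <- pmin(pmax(e2[live], .Machine$double.eps), 1)
      effd$e <- e2
    } else {
      Wd[link_idx] <- Wd[link_idx] * f
      for (j in cons) {
        s <- sum(Wd[, j])
        if (s > 0) Wd[, j] <- Wd[, j] / s
      }
    }
    sol <- tryCatch(solve_fluxes(web, Wd, Xd, effd), error = function(e) NULL)
    if (is.null(sol)) { n_infeasible <- n_infeasible + 1L; next }
    F_draws[d, ] <- sol$F[link_idx]
    G_draws[d, ] <- sol$G[cons]
  }
  if (n_infeasible == n) stop("all perturbation draws were infeasible")

  rel_dev <- function(draws, ref) {
    dev <- abs(sweep(draws, 2, ref)) / rep(pmax(ref, 1e-12), each = nrow(draws))
    data.frame(mean_rel_dev = colMeans(dev, na.rm = TRUE),
               cv = apply(draws, 2, function(x)
                 if (mean(x, na.rm = TRUE) > 0)
                   stats::sd(x, na.rm = TRUE) / mean(x, na.rm = TRUE) else 0))
  }
  per_link <- cbind(data.frame(resource_id = web$links$resource_id,
                               consumer_id = web$links$consumer_id),
                    rel_dev(F_draws, base$F[link_idx]))
  per_node <- cbind(data.frame(node_id = ids[cons]),
                    rel_dev(G_draws, base$G[cons]))
  rownames(per_link) <- rownames(per_node) <- NULL
  structure(list(parameter = parameter, v = v, n = n, seed = seed,
                 per_link = per_link, per_node = per_node,
                 mean_link_deviation = mean(per_link$mean_rel_dev),
                 n_infeasible = n_infeasible, n_clamped = n_clamped,
                 factors = if (trace) 1 + v * u else NULL),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(paste0("sensitivity_report: %s perturbed, v = %g, n = %d draws",
                     " (seed %s)\nmean link deviation %.4g; infeasible draws",
                     " %d; clamped values %d\n"),
              x$parameter, x$v, x$n, format(x$seed), x$mean_link_deviation,
              x$n_infeasible, x$n_clamped))
  invisible(x)
}
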