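# Ecosystem-process proxies: aggregate link fluxes into herbivory,
# detritivory, predation, totals, and a cross-web multifunctionality index.

process_resource_type <- c(herbivory = "plant", detritivory = "detritus",
                           predation = "animal")
process_consumer_guild <- c(herbivory = "herbivore", detritivory = "detritivore",
                            predation = "predator")

#' Flux-based proxy for one ecosystem process
#'
#' Under the default out-of-resource convention, herbivory is the summed flux
#' out of plant nodes, detritivory the flux out of detritus nodes, and
#' predation the flux out of animal nodes (the link flux F is defined as flux
#' out of the resource). The into-consumer convention instead sums flux into
#' consumers of the matching guild (herbivore, detritivore, predator) —
#' "energy flowing to all herbivores". Both are exposed because both
#' phrasings are in common use; the convention is recorded with the value.
#'
#' @param solution A `flux_solution`.
#' @param web The `food_web` it was solved on.
#' @param process One of `"herbivory"`, `"detritivory"`, `"predation"`.
#' @param convention `"out-of-resource"` (default) or `"into-consumer"`.
#' @return Single nonnegative flux value, with attribute `"convention"`.
#' @export
function_flux <- function(solution, web,
                          process = c("herbivory", "detritivory", "predation"),
                          convention = c("out-of-resource", "into-consumer")) {
  stopifnot(inherits(solution, "flux_solution"), inherits(web, "food_web"))
  process <- match.arg(process)
  convention <- match.arg(convention)
  nodes <- web$nodes
  val <- if (convention == "out-of-resource") {
    rows <- which(!is.na(nodes$resource_type) &
                    nodes$resource_type == process_resource_type[[process]])
    sum(solution$F[rows, , drop = FALSE])
  } else {
    cols <- which(!is.na(nodes$guild) &
                    nodes$guild == process_consumer_guild[[process]])
    sum(solution$F[, cols, drop = FALSE])
  }
  structure(val, convention = convention)
}

#' All process proxies of one solution
#'
#' @inheritParams function_flux
#' @param processes Character vector of process names.
#' @return Data frame `process, convention, value`.
#' @export
function_report <- function(solution, web,
                            convention = c("out-of-resource", "into-consumer"),
                            processes = c("herbivory", "detritivory", "predation")) {
  convention <- match.arg(convention)
  data.frame(process = processes, convention = convention,
             value = vapply(processes, function(p)
               as.numeric(function_flux(solution, web, p, convention)),
               numeric(1)))
}

#' Total flux through a solved web
#'
#' @param solution A `flux_solution`.
#' @return Sum of all link fluxes; at least as large as any single process
#'   proxy.
#' @export
total_flux <- function(solution) {
  stopifnot(inherits(solution, "flux_solution"))
  sum(solution$F)
}

#' Trophic multifunctionality across webs
#'
#' Standardizes each process across webs (z-score) and averages the z-scores
#' per web — one of several possible multifunctionality indices, useful for
#' ranking communities by their joint process rates. Processes with zero
#' variance across webs carry no ranking information and are dropped with a
#' warning; if no process varies, every web scores 0.
#'
#' @param reports A numeric matrix/data frame (webs in rows, processes in
#'   columns) or a list of equally named numeric vectors, one per web.
#' @param processes Optional subset of process columns to use.
#' @return Named numeric vector: one index per web.
#' @export
multifunctionality_index <- function(reports, processes = NULL) {
  if (is.list(reports) && !is.data.frame(reports))
    reports <- do.call(rbind, reports)
  m <- as.matrix(reports)
  if (nrow(m) < 2) stop("need at least two webs")
  if (!is.null(processes)) {
    missing <- setdiff(processes, colnames(m))
    if (length(missing)) stop("report lacks process(es): ",
                              paste(missing, collapse = ", "))
    m <- m[, processes, drop = FALSE]
  }
  sds <- apply(m, 2, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat))
    warning("zero variance across webs, dropped: ",
            paste(colnames(m)[flat], collapse = ", "), call. = FALSE)
  if (all(flat)) return(stats::setNames(rep(0, nrow(m)), rownames(m)))
  z <- scale(m[, !flat, drop = FALSE])
  stats::setNames(rowMeans(z), rownames(m))
}
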