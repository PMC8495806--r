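# Guild-structured synthetic communities, and the worked three-node chain
# fixture. The generator emulates a plot-scale arthropod community assessment:
# basal pools (plants, detritus) with biomass densities, and consumer guilds
# (detritivores, herbivores, omnivores, predators) with individual body
# masses drawn lognormally per guild, abundances, and guild-rule feeding
# links. Guild adjacency is acyclic, so generated webs are always DAGs and
# always energetically feasible.

guild_defaults <- function() {
  list(
    resource_type = c(plant = "plant", detritus = "detritus",
                      detritivore = "animal", herbivore = "animal",
                      omnivore = "animal", predator = "animal"),
    # log10 body-mass mean/sd (mg fresh) for consumer guilds
    mass_log10_mean = c(detritivore = 0.0, herbivore = 0.5,
                        omnivore = 1.0, predator = 1.5),
    mass_log10_sd = c(detritivore = 0.4, herbivore = 0.4,
                      omnivore = 0.4, predator = 0.4),
    # expected individuals per m2
    abundance_lambda = c(detritivore = 80, herbivore = 60,
                         omnivore = 20, predator = 8),
    # basal biomass density, lognormal on the natural-log scale (mg/m2)
    basal_biomass_logmean = c(plant = log(2e4), detritus = log(5e4)),
    basal_biomass_logsd = c(plant = 0.3, detritus = 0.3),
    # who may eat whom
    diet = list(detritivore = "detritus",
                herbivore = "plant",
                omnivore = c("plant", "detritus", "herbivore", "detritivore"),
                predator = c("herbivore", "detritivore", "omnivore")))
}

#' Configuration for the synthetic-web generator
#'
#' @param n_plants,n_detritus,n_detritivores,n_herbivores,n_omnivores,n_predators
#'   Node counts per guild (>= 0; at least one basal and one consumer guild
#'   must be populated).
#' @param connection_prob Probability that a permitted guild-to-guild link is
#'   realized for a given consumer-resource pair; each consumer is guaranteed
#'   at least one resource (re-sampled if the draw leaves it unconnected).
#'   Set to 1 for a fully guild-connected web, under which within-guild nodes
#'   share identical resource and consumer sets (a strictly parallel
#'   partition).
#' @param temperature_C Ambient temperature.
#' @param seed Integer seed; webs are reproducible under a fixed seed.
#' @param guilds Advanced: override of the per-guild parameter list (body-mass
#'   and abundance distributions, basal biomasses, diet rules).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_plants = 4, n_detritus = 2, n_detritivores = 3,
                             n_herbivores = 3, n_omnivores = 2, n_predators = 3,
                             connection_prob = 0.6, temperature_C = 20,
                             seed = 1, guilds = guild_defaults()) {
  counts <- c(plant = n_plants, detritus = n_detritus,
              detritivore = n_detritivores, herbivore = n_herbivores,
              omnivore = n_omnivores, predator = n_predators)
  if (any(counts < 0)) stop("guild counts must be >= 0")
  if (connection_prob < 0 || connection_prob > 1)
    stop("connection_prob must lie in [0, 1]")
  structure(list(counts = counts, connection_prob = connection_prob,
                 temperature_C = temperature_C, seed = seed, guilds = guilds),
            class = "generator_config")
}

#' Generate a guild-structured synthetic food web
#'
#' @param config A [generator_config()].
#' @param compute_losses Fill per-node metabolic losses from the individual
#'   body masses with `regressions` (default: the bundled terrestrial
#'   invertebrate coefficients).
#' @param regressions Passed to [node_losses()].
#' @return A `food_web` that passes [validate_web()] with no diagnostics and
#'   is always solvable (guild adjacency is acyclic and every consumer has a
#'   positive-biomass diet).
#' @export
generate_web <- function(config = generator_config(), compute_losses = TRUE,
                         regressions = default_metabolic_regressions()) {
  stopifnot(inherits(config, "generator_config"))
  g <- config$guilds
  counts <- config$counts
  basal_guilds <- intersect(names(counts)[counts > 0], c("plant", "detritus"))
  consumer_guilds <- intersect(names(counts)[counts > 0], names(g$diet))
  if (!length(basal_guilds)) stop("impossible config: no basal guild populated")
  if (!length(consumer_guilds)) stop("impossible config: no consumer guild populated")
  for (cg in consumer_guilds)
    if (!any(counts[intersect(g$diet[[cg]], names(counts))] > 0))
      stop("impossible config: guild '", cg, "' has no permitted resource guild")

  withr::with_seed(config$seed, {
    nodes <- list(); body_masses <- list()
    for (guild in names(counts)) {
      for (k in seq_len(counts[[guild]])) {
        id <- sprintf("%s_%d", guild, k)
        if (guild %in% c("plant", "detritus")) {
          nodes[[id]] <- data.frame(
            node_id = id, name = id, guild = guild,
            resource_type = g$resource_type[[guild]],
            biomass = stats::rlnorm(1, g$basal_biomass_logmean[[guild]],
                                    g$basal_biomass_logsd[[guild]]),
            abundance = NA_real_, mean_body_mass = NA_real_, loss = NA_real_)
        } else {
          ab <- max(2L, stats::rpois(1, g$abundance_lambda[[guild]]))
          masses <- 10^stats::rnorm(ab, g$mass_log10_mean[[guild]],
                                    g$mass_log10_sd[[guild]])
          body_masses[[id]] <- masses
          nodes[[id]] <- data.frame(
            node_id = id, name = id, guild = guild,
            resource_type = g$resource_type[[guild]],
            biomass = sum(masses),  # coherent: abundance * mean mass
            abundance = ab, mean_body_mass = mean(masses), loss = NA_real_)
        }
      }
    }
    nodes <- do.call(rbind, nodes)

    links <- list()
    for (cg in consumer_guilds) {
      resources <- nodes$node_id[nodes$guild %in% g$diet[[cg]]]
      for (c_id in nodes$node_id[nodes$guild == cg]) {
        pick <- resources[stats::runif(length(resources)) < config$connection_prob]
        if (!length(pick)) pick <- sample(resources, 1)
        links[[c_id]] <- data.frame(resource_id = pick, consumer_id = c_id,
                                    active_weight = 1)
      }
    }
    links <- do.call(rbind, links)
    rownames(nodes) <- rownames(links) <- NULL

    web <- build_web(nodes, links, losses_per_unit_biomass = FALSE,
                     temperature_C = config$temperature_C,
                     body_masses = body_masses)
    if (compute_losses) web <- node_losses(web, regressions)
    web
  })
}

#' The worked three-node chain fixture
#'
#' A plant -> herbivore -> predator chain with whole-node metabolic demands
#' X_herbivore = 2 and X_predator = 1 in abstract energy units. With the
#' bundled default efficiencies, solving it by hand from the top gives
#' `F(herbivore -> predator) = 1/0.906` and
#' `F(plant -> herbivore) = (2 + 1/0.906)/0.545`.
#'
#' @return A `food_web`.
#' @export
fixture_chain <- function() {
  build_web(
    data.frame(node_id = c("plant", "herbivore", "predator"),
               guild = c("plant", "herbivore", "predator"),
               resource_type = c("plant", "animal", "animal"),
               biomass = c(1000, 100, 10),
               loss = c(NA, 2, 1)),
    data.frame(resource_id = c("plant", "herbivore"),
               consumer_id = c("herbivore", "predator")),
    losses_per_unit_biomass = FALSE, temperature_C = 20)
}
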