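test_that("build_web assembles the three-node chain with derived basal flags", {
  web <- fixture_chain()
  expect_s3_class(web, "food_web")
  expect_equal(nrow(web$nodes), 3)
  expect_equal(nrow(web$links), 2)
  expect_equal(web$nodes$is_basal, c(TRUE, FALSE, FALSE))
})

test_that("build_web rejects malformed inputs with informative errors", {
  nodes <- data.frame(node_id = c("sp1", "sp1"), biomass = c(1, 1))
  links <- data.frame(resource_id = "sp1", consumer_id = "sp1",
                      active_weight = 0.1)
  expect_error(build_web(nodes, links), "sp1")

  expect_error(build_web(data.frame(node_id = "a", biomass = 1), NULL),
               "no consumer node")

  expect_error(
    build_web(data.frame(node_id = c("a", "b"), biomass = c(1, 1)),
              data.frame(resource_id = "a", consumer_id = "ghost")),
    "ghost")

  expect_error(
    build_web(data.frame(node_id = c("a", "b"), biomass = c(1, -1)),
              data.frame(resource_id = "a", consumer_id = "b")),
    "biomass")

  # user basal flag contradicting topology
  expect_error(
    build_web(data.frame(node_id = c("a", "b"), biomass = c(1, 1),
                         is_basal = c(TRUE, TRUE)),
              data.frame(resource_id = "a", consumer_id = "b")),
    "is_basal")

  # cannibalistic self-link without an explicit active weight
  expect_error(
    build_web(data.frame(node_id = c("a", "b"), biomass = c(1, 1)),
              data.frame(resource_id = c("a", "b"), consumer_id = c("b", "b"))),
    "active_weight")
})

test_that("validate_web flags the documented hygiene problems", {
  # consumer whose only resource has biomass 0, passive preferences intended
  web <- build_web(data.frame(node_id = c("r", "c"), biomass = c(0, 5),
                              loss = c(NA, 1)),
                   data.frame(resource_id = "r", consumer_id = "c"),
                   losses_per_unit_biomass = FALSE)
  d <- validate_web(web, use_biomass = TRUE)
  expect_true(any(d$severity == "error" & d$code == "zero_biomass_diet"))

  # consumer with neither loss nor body-mass data
  web2 <- build_web(data.frame(node_id = c("r", "c"), biomass = c(10, 5)),
                    data.frame(resource_id = "r", consumer_id = "c"))
  d2 <- validate_web(web2)
  expect_true(any(d2$code == "no_metabolic_route" & d2$severity == "error"))
  expect_match(d2$message[d2$code == "no_metabolic_route"], "metabolic demand")

  # node unreachable from any basal node
  web3 <- build_web(
    data.frame(node_id = c("r", "c", "island", "island2"),
               biomass = c(10, 5, 1, 1), loss = c(NA, 1, 1, 1)),
    data.frame(resource_id = c("r", "island", "island2"),
               consumer_id = c("c", "island2", "island"),
               active_weight = 1),
    losses_per_unit_biomass = FALSE)
  expect_true(any(validate_web(web3)$code == "unreachable"))

  # fully specified chain is clean
  expect_equal(nrow(validate_web(fixture_chain())), 0)
})

test_that("topological order runs from top consumers down to resources", {
  expect_equal(topological_order(fixture_chain()),
               c("predator", "herbivore", "plant"))

  # mutual predation: cycle report naming both nodes
  web <- build_web(
    data.frame(node_id = c("plant", "a", "b"), biomass = c(10, 5, 5),
               loss = c(NA, 1, 1)),
    data.frame(resource_id = c("plant", "a", "b"),
               consumer_id = c("a", "b", "a"), active_weight = 1),
    losses_per_unit_biomass = FALSE)
  rep <- topological_order(web)
  expect_s3_class(rep, "flux_cycle_report")
  expect_setequal(rep$cycle_nodes, c("a", "b"))
})

test_that("topological order puts every consumer before all its resources", {
  for (s in 1:10) {
    web <- generate_web(generator_config(seed = s), compute_losses = FALSE)
    ord <- topological_order(web)
    pos <- match(ord, ord)
    names(pos) <- ord
    ok <- mapply(function(r, c) pos[c] < pos[r],
                 web$links$resource_id, web$links$consumer_id)
    expect_true(all(ok), info = paste("seed", s))
  }
})

test_that("identity partition returns an equal web", {
  web <- omnivore_web()
  part <- setNames(web$nodes$node_id, web$nodes$node_id)
  agg <- aggregate_nodes(web, part)
  expect_equal(agg$nodes, web$nodes)
  expect_equal(sorted_links(agg), sorted_links(web))
  expect_equal(attr(agg, "aggregation")$classification, "parallel")
})

test_that("aggregation conserves biomass and per-node losses, and combines weights", {
  web <- omnivore_web()
  part <- c(plant1 = "plants", plant2 = "plants", detritus = "detritus",
            herb = "herb", omni = "omni", pred = "pred")
  agg <- aggregate_nodes(web, part)
  expect_equal(sum(agg$nodes$biomass), sum(web$nodes$biomass))
  expect_equal(sum(agg$nodes$loss, na.rm = TRUE),
               sum(web$nodes$loss, na.rm = TRUE))
  # both plants fed to herb with weight 1 -> combined weight is 1
  w <- agg$links$active_weight[agg$links$resource_id == "plants" &
                                 agg$links$consumer_id == "herb"]
  expect_equal(w, 1)

  # conflicting resource types refuse to merge
  expect_error(aggregate_nodes(web, c(plant1 = "x", plant2 = "x",
                                      detritus = "x", herb = "herb",
                                      omni = "omni", pred = "pred")),
               "resource types")
})

test_that("merging two parallel predators preserves flux into the merged node", {
  nodes <- data.frame(node_id = c("plant", "herb1", "herb2", "predA", "predB"),
                      guild = c("plant", "herbivore", "herbivore",
                                "predator", "predator"),
                      resource_type = c("plant", "animal", "animal",
                                        "animal", "animal"),
                      biomass = c(1000, 60, 40, 10, 5),
                      loss = c(NA, 2, 1.5, 1, 0.5))
  links <- data.frame(resource_id = c("plant", "plant", "herb1", "herb2",
                                      "herb1", "herb2"),
                      consumer_id = c("herb1", "herb2", "predA", "predA",
                                      "predB", "predB"))
  web <- build_web(nodes, links, losses_per_unit_biomass = FALSE)
  sol <- solve_fluxes(web)
  flux_into_preds <- sum(sol$F[, c("predA", "predB")])

  agg <- aggregate_nodes(web, c(plant = "plant", herb1 = "herb1",
                                herb2 = "herb2", predA = "pred", predB = "pred"))
  expect_equal(attr(agg, "aggregation")$classification, "parallel")
  sol2 <- solve_fluxes(agg)
  expect_equal(sum(sol2$F[, "pred"]), flux_into_preds, tolerance = 1e-12)

  # serial merge (herbivore with its predator) warns
  expect_warning(
    aggregate_nodes(web, c(plant = "plant", herb1 = "m", herb2 = "herb2",
                           predA = "m", predB = "predB")),
    "serial")
})

test_that("a web round-trips through write and read", {
  web <- generate_web(generator_config(seed = 7))
  nodes_f <- withr::local_tempfile(fileext = ".csv")
  links_f <- withr::local_tempfile(fileext = ".csv")
  bm_f <- withr::local_tempfile(fileext = ".csv")
  write_food_web(web, nodes_f, links_f, bm_f)
  back <- read_food_web(nodes_f, links_f, bm_f,
                        losses_per_unit_biomass = web$losses_per_unit_biomass,
                        temperature_C = web$temperature_C)
  expect_equal(back$nodes, web$nodes, tolerance = 1e-12)
  expect_equal(sorted_links(back), sorted_links(web), tolerance = 1e-12)
  for (id in names(web$body_masses))
    expect_equal(back$body_masses[[id]], web$body_masses[[id]], tolerance = 1e-12)
})
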