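# Shared fixtures, built in code.

# hand-derived fixture-chain fluxes: sequential application of the balance
# from the top, with the bundled default efficiencies
CHAIN_F_HERB_PRED <- 1 / 0.906
CHAIN_F_PLANT_HERB <- (2 + 1 / 0.906) / 0.545

# six nodes with an omnivore feeding on both a herbivore and a plant
omnivore_web <- function() {
  build_web(
    data.frame(node_id = c("plant1", "plant2", "detritus", "herb", "omni", "pred"),
               guild = c("plant", "plant", "detritus", "herbivore", "omnivore",
                         "predator"),
               resource_type = c("plant", "plant", "detritus", "animal",
                                 "animal", "animal"),
               biomass = c(800, 400, 2000, 60, 30, 12),
               loss = c(NA, NA, NA, 3, 2, 1)),
    data.frame(resource_id = c("plant1", "plant2", "plant1", "herb",
                               "detritus", "herb", "omni"),
               consumer_id = c("herb", "herb", "omni", "omni",
                               "omni", "pred", "pred")),
    losses_per_unit_biomass = FALSE)
}

# relative elementwise difference, 0 where both entries are 0
rel_diff <- function(a, b) {
  d <- abs(a - b)
  s <- pmax(abs(a), abs(b))
  out <- ifelse(s == 0, 0, d / s)
  max(out)
}

sorted_links <- function(web) {
  l <- web$links
  l <- l[order(l$consumer_id, l$resource_id), ]
  rownames(l) <- NULL
  l
}

# uniform efficiency assignment (e.g. the lossless limit e = 1)
uniform_eff <- function(web, e_val = 1) {
  e <- rep(e_val, nrow(web$nodes))
  names(e) <- web$nodes$node_id
  structure(list(level = "resource", e = e, reference_temperature_C = 20,
                 source = "test"), class = "efficiency_assignment")
}
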