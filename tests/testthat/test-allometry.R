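test_that("length_to_mass evaluates the declared power law", {
  # identity regression: a = 0, b = 1 on log10 scale
  r1 <- length_mass_regression("t", "log10", intercept = 0, exp_length = 1)
  expect_equal(length_to_mass(10, r1), 10)

  # length + width: a = 0, b = 1, b2 = 1 -> mass = L * W
  r2 <- length_mass_regression("t", "log10", 0, 1, exp_width = 1)
  expect_equal(length_to_mass(10, r2, width = 2), 20)
  expect_error(length_to_mass(10, r2), "width")
  expect_error(length_to_mass(-1, r1), "length")

  # bundled default coefficients vs an independent hand evaluation
  reg <- default_length_mass_regressions()[["generic_arthropod"]]
  expect_equal(length_to_mass(5.0, reg),
               10^(-1.02 + 2.53 * log10(5.0)), tolerance = 1e-12)

  # natural-log regression and dry-basis conversion agree with direct math
  r3 <- length_mass_regression("t", "ln", intercept = 0.5, exp_length = 2,
                               mass_basis = "dry", dry_to_fresh_factor = 4)
  expect_equal(length_to_mass(3, r3), exp(0.5 + 2 * log(3)) * 4,
               tolerance = 1e-12)
})

test_that("dry_to_fresh applies factors and regression forms", {
  expect_equal(dry_to_fresh(2, 4), 8)
  expect_equal(dry_to_fresh(0, 4), 0)
  expect_equal(dry_to_fresh(2), 2)  # default factor 1: no hidden conversion
  expect_error(dry_to_fresh(2, -1), "factor")
  expect_error(dry_to_fresh(-1, 2), "dry mass")
  conv <- list(scale = "log10", intercept = 0.6, slope = 1.1)
  expect_equal(dry_to_fresh(2, conv), 10^(0.6 + 1.1 * log10(2)),
               tolerance = 1e-12)
})

test_that("metabolic_rate follows the Boltzmann-Arrhenius power law", {
  ident <- metabolic_regression("t", ln_x0 = 0, a = 1, E = 0)
  expect_equal(metabolic_rate(2, 20, ident), 2)

  r34 <- metabolic_regression("t", 0, 0.75, 0)
  expect_equal(metabolic_rate(16, 20, r34), 8)

  # temperature monotonicity for any E > 0
  warm <- metabolic_regression("t", 0, 0.75, 0.69)
  expect_gt(metabolic_rate(5, 25, warm), metabolic_rate(5, 15, warm))

  # scale consistency: adding ln(c) to the intercept multiplies X by c
  r_a <- metabolic_regression("t", 1.2, 0.7, 0.5)
  r_b <- metabolic_regression("t", 1.2 + log(3), 0.7, 0.5)
  expect_equal(metabolic_rate(7, 18, r_b), 3 * metabolic_rate(7, 18, r_a),
               tolerance = 1e-14)

  expect_error(metabolic_rate(0, 20, ident), "mass")
  expect_error(metabolic_rate(1, -300, ident), "temperature")
})

test_that("node_losses sums per-capita rates over individuals", {
  ident <- metabolic_regression("t", 0, 1, 0)
  web <- build_web(data.frame(node_id = c("r", "c"), biomass = c(10, 2)),
                   data.frame(resource_id = "r", consumer_id = "c"),
                   losses_per_unit_biomass = FALSE,
                   body_masses = list(c = c(1, 1)))
  got <- node_losses(web, ident)
  expect_equal(got$nodes$loss, c(0, 2))  # basal loss 0; 2 * X(1)
  expect_false(got$losses_per_unit_biomass)

  # field-metabolic-rate multiplier scales losses exactly threefold
  got3 <- node_losses(web, ident, fmr_multiplier = 3)
  expect_equal(got3$nodes$loss, 3 * got$nodes$loss)
})

test_that("mean-mass fallback matches the hand computation and warns", {
  reg <- metabolic_regression("t", 0, 0.75, 0)
  web_ind <- build_web(data.frame(node_id = c("r", "c"), biomass = c(10, 4)),
                       data.frame(resource_id = "r", consumer_id = "c"),
                       losses_per_unit_biomass = FALSE,
                       body_masses = list(c = c(1, 3)))
  expect_equal(node_losses(web_ind, reg)$nodes$loss[2], 1^0.75 + 3^0.75,
               tolerance = 1e-14)

  web_mean <- build_web(data.frame(node_id = c("r", "c"), biomass = c(10, 4),
                                   abundance = c(NA, 2),
                                   mean_body_mass = c(NA, 2)),
                        data.frame(resource_id = "r", consumer_id = "c"),
                        losses_per_unit_biomass = FALSE)
  expect_warning(got <- node_losses(web_mean, reg), "mean-mass")
  expect_equal(got$nodes$loss[2], 2 * 2^0.75, tolerance = 1e-14)

  # the fallback overestimates the demand of the unequal-mass population
  expect_gt(2 * 2^0.75, 1^0.75 + 3^0.75)

  # ...and equals the individual sum exactly when all masses are equal
  web_eq <- build_web(data.frame(node_id = c("r", "c"), biomass = c(10, 4)),
                      data.frame(resource_id = "r", consumer_id = "c"),
                      losses_per_unit_biomass = FALSE,
                      body_masses = list(c = c(2, 2)))
  expect_equal(node_losses(web_eq, reg)$nodes$loss[2], got$nodes$loss[2],
               tolerance = 1e-14)

  # no route to a loss at all
  web_none <- build_web(data.frame(node_id = c("r", "c"), biomass = c(10, 4)),
                        data.frame(resource_id = "r", consumer_id = "c"))
  expect_error(node_losses(web_none, reg), "no route")
})

test_that("many small individuals demand more than one large one of equal biomass", {
  # Jensen property for a concave mass exponent 0 < a < 1
  reg <- metabolic_regression("t", 0, 0.695071, 0)
  set.seed(42)
  for (i in 1:20) {
    masses <- 10^runif(sample(3:12, 1), -1, 1.5)
    joint <- sum(metabolic_rate(masses, 20, reg))
    single <- metabolic_rate(sum(masses), 20, reg)
    expect_gt(joint, single)
  }
})

test_that("pre-supplied per-biomass losses convert to whole-node values", {
  ident <- metabolic_regression("t", 0, 1, 0)
  web <- build_web(data.frame(node_id = c("r", "c"), biomass = c(10, 5),
                              loss = c(NA, 0.4)),
                   data.frame(resource_id = "r", consumer_id = "c"),
                   losses_per_unit_biomass = TRUE)
  got <- node_losses(web, ident)
  expect_equal(got$nodes$loss[2], 0.4 * 5)
  expect_false(got$losses_per_unit_biomass)
})
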