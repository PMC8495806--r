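# Allometry: body dimensions -> fresh body mass, and body mass + temperature
# -> per-capita metabolic rate (the loss term X of the flux balance).
#
# All regression coefficients are data, not code: constructors take explicit
# coefficients and the bundled tables under inst/extdata are editable
# placeholder defaults with provenance columns. The log convention (log10 vs
# natural log) is an explicit field of every regression record — it is never
# inferred.

BOLTZMANN_EV <- 8.62e-5  # eV per Kelvin

#' Length-mass regression record
#'
#' @param taxon Key naming the taxon the regression applies to.
#' @param scale `"log10"` or `"ln"`: the logarithm in which the regression was
#'   fitted.
#' @param intercept Intercept a on the chosen log scale.
#' @param exp_length Length exponent b (> 0).
#' @param exp_width Optional width exponent b2; when given, [length_to_mass()]
#'   requires a width measurement.
#' @param mass_basis `"fresh"` or `"dry"`: what the regression predicts. Dry
#'   predictions are converted with `dry_to_fresh_factor` before return.
#' @param dry_to_fresh_factor Multiplicative dry-to-fresh conversion (default
#'   1: no hidden conversion; override explicitly when `mass_basis = "dry"`).
#' @param unit_in,unit_out Declared input (length) and output (mass) units.
#' @param source Provenance note.
#' @return A `length_mass_regression` object.
#' @export
length_mass_regression <- function(taxon, scale = c("log10", "ln"), intercept,
                                   exp_length, exp_width = NA_real_,
                                   mass_basis = c("fresh", "dry"),
                                   dry_to_fresh_factor = 1,
                                   unit_in = "mm", unit_out = "mg",
                                   source = "unspecified") {
  scale <- match.arg(scale)
  mass_basis <- match.arg(mass_basis)
  if (!is.finite(exp_length) || exp_length <= 0) stop("length exponent b must be > 0")
  if (!nzchar(unit_in) || !nzchar(unit_out)) stop("units must be declared")
  if (dry_to_fresh_factor <= 0) stop("dry-to-fresh factor must be > 0")
  structure(list(taxon = taxon, scale = scale, intercept = intercept,
                 exp_length = exp_length, exp_width = exp_width,
                 mass_basis = mass_basis,
                 dry_to_fresh_factor = dry_to_fresh_factor,
                 unit_in = unit_in, unit_out = unit_out, source = source),
            class = "length_mass_regression")
}

#' Convert body length to fresh body mass
#'
#' Evaluates the power law `mass = 10^(a + b*log10(L) [+ b2*log10(W)])`
#' (analogously with the natural log) and applies the declared dry-to-fresh
#' conversion when the regression predicts dry mass.
#'
#' @param length Body length (> 0), in the regression's input unit.
#' @param regression A [length_mass_regression()].
#' @param width Optional body width; required iff the regression has a width
#'   exponent.
#' @return Fresh body mass in the regression's output unit. Vectorised over
#'   `length` (and `width`).
#' @export
length_to_mass <- function(length, regression, width = NULL) {
  stopifnot(inherits(regression, "length_mass_regression"))
  if (any(!is.finite(length)) || any(length <= 0)) stop("length must be > 0")
  has_width <- is.finite(regression$exp_width)
  if (has_width && is.null(width))
    stop("regression for '", regression$taxon, "' requires a width measurement")
  if (!has_width && !is.null(width))
    stop("regression for '", regression$taxon, "' has no width exponent")
  lg <- if (regression$scale == "log10") log10 else log
  expo <- if (regression$scale == "log10") function(x) 10^x else exp
  y <- regression$intercept + regression$exp_length * lg(length)
  if (has_width) {
    if (any(width <= 0)) stop("width must be > 0")
    y <- y + regression$exp_width * lg(width)
  }
  mass <- expo(y)
  if (regression$mass_basis == "dry")
    mass <- dry_to_fresh(mass, regression$dry_to_fresh_factor)
  mass
}

#' Convert dry mass to fresh mass
#'
#' @param dry_mass Dry mass (>= 0).
#' @param conversion Either a positive multiplicative factor (the default 1
#'   performs no conversion and must be overridden deliberately) or a
#'   regression list `list(scale = "log10"|"ln", intercept, slope)` evaluated
#'   as `fresh = expo(intercept + slope * lg(dry))`.
#' @return Fresh mass.
#' @export
dry_to_fresh <- function(dry_mass, conversion = 1) {
  if (any(dry_mass < 0)) stop("dry mass must be >= 0")
  if (is.numeric(conversion) && length(conversion) == 1) {
    if (conversion <= 0) stop("conversion factor must be > 0")
    return(dry_mass * conversion)
  }
  stopifnot(is.list(conversion),
            all(c("scale", "intercept", "slope") %in% names(conversion)))
  lg <- if (conversion$scale == "log10") log10 else log
  expo <- if (conversion$scale == "log10") function(x) 10^x else exp
  out <- ifelse(dry_mass == 0, 0,
                expo(conversion$intercept + conversion$slope * lg(dry_mass)))
  as.numeric(out)
}

#' Metabolic-rate regression record (Boltzmann-Arrhenius power law)
#'
#' Encodes `ln X = ln_x0 + a * ln(M) - E / (k * T_Kelvin)` with the Boltzmann
#' constant fixed at 8.62e-5 eV/K. Temperature enters in Kelvin internally;
#' every interface of this package accepts degrees Celsius.
#'
#' @param group Key naming the taxonomic/functional group.
#' @param ln_x0 Natural-log intercept.
#' @param a Mass exponent (per-capita rate rises with mass when a > 0).
#' @param E Activation energy in eV (>= 0; rate rises with temperature when
#'   E > 0).
#' @param unit_mass Declared input mass unit.
#' @param unit_out Declared output unit (energy per individual per time).
#' @param source Provenance note.
#' @return A `metabolic_regression` object.
#' @export
metabolic_regression <- function(group, ln_x0, a, E,
                                 unit_mass = "mg", unit_out = "J/h",
                                 source = "unspecified") {
  if (!is.finite(E) || E < 0) stop("activation energy must be >= 0")
  if (!nzchar(unit_mass) || !nzchar(unit_out)) stop("units must be declared")
  structure(list(group = group, ln_x0 = ln_x0, a = a, E = E,
                 k = BOLTZMANN_EV, unit_mass = unit_mass, unit_out = unit_out,
                 source = source),
            class = "metabolic_regression")
}

#' Per-capita metabolic rate from body mass and temperature
#'
#' @param mass Fresh body mass (> 0), in the regression's mass unit.
#' @param temperature_C Ambient temperature in degrees Celsius (> -273.15).
#' @param regression A [metabolic_regression()].
#' @return Per-capita metabolic rate X (> 0) in the regression's output unit.
#'   Vectorised over `mass`.
#' @export
metabolic_rate <- function(mass, temperature_C, regression) {
  stopifnot(inherits(regression, "metabolic_regression"))
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("mass must be > 0")
  if (temperature_C <= -273.15) stop("temperature below absolute zero")
  t_kelvin <- temperature_C + 273.15
  exp(regression$ln_x0 + regression$a * log(mass) -
        regression$E / (regression$k * t_kelvin))
}

#' Bundled default metabolic regressions
#'
#' Reads the editable coefficient table shipped under `extdata/`. The bundled
#' values are placeholder defaults for terrestrial invertebrates (attributed
#' to Ehnes et al. 2011; J/h from mg fresh mass) and should be replaced with
#' coefficients verified against the original sources for real analyses.
#'
#' @param path Optional path to a user table with the same columns
#'   (`group, ln_x0, a, activation_energy_eV, unit_mass, unit_out, source`).
#' @return Named list of [metabolic_regression()] objects, one per group key,
#'   plus a `"default"` entry used for guilds without their own row.
#' @export
default_metabolic_regressions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "metabolic_regressions.csv",
                        package = "trophicflux", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i)
    metabolic_regression(tab$group[i], tab$ln_x0[i], tab$a[i],
                         tab$activation_energy_eV[i],
                         unit_mass = tab$unit_mass[i], unit_out = tab$unit_out[i],
                         source = tab$source[i]))
  names(out) <- tab$group
  out
}

#' Bundled default length-mass regressions
#'
#' Reads the editable length-mass coefficient table shipped under `extdata/`
#' (placeholder defaults marked for replacement from the cited collections).
#'
#' @param path Optional path to a user table with the same columns.
#' @return Named list of [length_mass_regression()] objects keyed by taxon.
#' @export
default_length_mass_regressions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "length_mass_regressions.csv",
                        package = "trophicflux", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i)
    length_mass_regression(tab$taxon[i], tab$scale[i], tab$intercept[i],
                           tab$exp_length[i],
                           exp_width = if (is.na(tab$exp_width[i])) NA_real_
                                       else tab$exp_width[i],
                           mass_basis = tab$mass_basis[i],
                           dry_to_fresh_factor = tab$dry_to_fresh_factor[i],
                           unit_in = tab$unit_in[i], unit_out = tab$unit_out[i],
                           source = tab$source[i]))
  names(out) <- tab$taxon
  out
}

resolve_regression <- function(regressions, guild) {
  if (inherits(regressions, "metabolic_regression")) return(regressions)
  r <- if (!is.na(guild) && guild %in% names(regressions)) regressions[[guild]]
       else regressions[["default"]]
  if (is.null(r)) stop("no metabolic regression for guild '", guild,
                       "' and no 'default' entry")
  r
}

#' Fill per-node metabolic losses of a food web
#'
#' Computes each consumer node's whole-node metabolic demand X: the sum of
#' per-capita rates over its individual body masses when those are available,
#' or `abundance * X(mean mass)` as a mean-mass fallback (with a warning,
#' since the mass-rate power law is nonlinear and the fallback overestimates
#' the demand of a size-structured population). Nodes with a pre-supplied
#' loss keep it (converted to a whole-node value if the web declared losses
#' per unit biomass). Basal nodes get loss 0: the approach quantifies energy
#' flowing out of, not into, the basal resources.
#'
#' @param web A `food_web`.
#' @param regressions A single [metabolic_regression()] applied to every
#'   consumer, or a named list keyed by guild (with an optional `"default"`).
#' @param fmr_multiplier Scalar >= 0 applied to all computed losses; set to ~3
#'   to approximate field rather than basal metabolic rates.
#' @return The web with `nodes$loss` filled on a whole-node basis and
#'   `losses_per_unit_biomass = FALSE`.
#' @export
node_losses <- function(web, regressions = default_metabolic_regressions(),
                        fmr_multiplier = 1) {
  stopifnot(inherits(web, "food_web"))
  if (!is.finite(fmr_multiplier) || fmr_multiplier < 0)
    stop("fmr_multiplier must be >= 0")
  nodes <- web$nodes
  loss <- numeric(nrow(nodes))
  used_fallback <- character()
  for (i in seq_len(nrow(nodes))) {
    if (nodes$is_basal[i]) { loss[i] <- 0; next }
    id <- nodes$node_id[i]
    masses <- web$body_masses[[id]]
    if (!is.null(masses)) {
      reg <- resolve_regression(regressions, nodes$guild[i])
      loss[i] <- fmr_multiplier * sum(metabolic_rate(masses, web$temperature_C, reg))
    } else if (!is.na(nodes$loss[i])) {
      # a measured loss beats the mean-mass approximation
      loss[i] <- if (web$losses_per_unit_biomass)
        nodes$loss[i] * nodes$biomass[i] else nodes$loss[i]
    } else if (!is.na(nodes$mean_body_mass[i]) && !is.na(nodes$abundance[i])) {
      reg <- resolve_regression(regressions, nodes$guild[i])
      used_fallback <- c(used_fallback, id)
      loss[i] <- fmr_multiplier * nodes$abundance[i] *
        metabolic_rate(nodes$mean_body_mass[i], web$temperature_C, reg)
    } else {
      stop("consumer '", id, "' has no route to a metabolic loss",
           " (no body masses, no mean mass + abundance, no pre-supplied loss)")
    }
  }
  if (length(used_fallback))
    warning("mean-mass fallback used for: ", paste(used_fallback, collapse = ", "),
            " (the mass-rate power law is nonlinear; individual masses are",
            " preferable)", call. = FALSE)
  web$nodes$loss <- loss
  web$losses_per_unit_biomass <- FALSE
  web
}
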