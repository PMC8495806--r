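# Readers and writers for the delimited-text dialects, run configuration,
# and provenance. All files are comma-separated, dot-decimal, UTF-8, with
# "#" comment headers.

header_comment <- "# comma-separated, dot-decimal, UTF-8"

write_csv_commented <- function(df, file, comment = header_comment) {
  con <- file(file, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(comment, con)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE, na = "")
}

read_table_file <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE,
                  strip.white = TRUE)
}

#' Read a food web from node/link tables
#'
#' @param nodes_file CSV with columns
#'   `node_id,name,guild,resource_type,biomass,abundance,mean_body_mass,loss`
#'   (optional columns may be empty or absent).
#' @param links_file CSV with columns `resource_id,consumer_id,active_weight`.
#' @param body_mass_file Optional long-format CSV `node_id,body_mass` with one
#'   row per individual.
#' @inheritParams build_web
#' @return A `food_web`.
#' @export
read_food_web <- function(nodes_file, links_file, body_mass_file = NULL,
                          losses_per_unit_biomass = TRUE, temperature_C = 20,
                          units = default_units()) {
  nodes <- read_table_file(nodes_file)
  links <- read_table_file(links_file)
  body_masses <- NULL
  if (!is.null(body_mass_file)) {
    bm <- read_table_file(body_mass_file)
    body_masses <- split(as.numeric(bm$body_mass), as.character(bm$node_id))
  }
  build_web(nodes, links, losses_per_unit_biomass = losses_per_unit_biomass,
            temperature_C = temperature_C, units = units,
            body_masses = body_masses)
}

#' Write a food web to node/link tables
#'
#' @param web A `food_web`.
#' @param nodes_file,links_file Output paths.
#' @param body_mass_file Optional path for the long-format individual
#'   body-mass table (written only when the web carries individual masses).
#' @return Invisibly, the paths written.
#' @export
write_food_web <- function(web, nodes_file, links_file, body_mass_file = NULL) {
  stopifnot(inherits(web, "food_web"))
  write_csv_commented(web$nodes, nodes_file)
  write_csv_commented(web$links, links_file)
  paths <- c(nodes_file, links_file)
  if (!is.null(body_mass_file) && length(web$body_masses)) {
    bm <- do.call(rbind, lapply(names(web$body_masses), function(id)
      data.frame(node_id = id, body_mass = web$body_masses[[id]])))
    write_csv_commented(bm, body_mass_file)
    paths <- c(paths, body_mass_file)
  }
  invisible(paths)
}

#' Export link fluxes of a solution
#'
#' @param solution A `flux_solution`.
#' @param web The `food_web` it was solved on.
#' @param file Output CSV path (`resource_id,consumer_id,flux`).
#' @return Invisibly, the exported data frame.
#' @export
write_flux_table <- function(solution, web, file) {
  ids <- node_ids(web)
  df <- data.frame(resource_id = web$links$resource_id,
                   consumer_id = web$links$consumer_id,
                   flux = solution$F[cbind(match(web$links$resource_id, ids),
                                           match(web$links$consumer_id, ids))])
  write_csv_commented(df, file)
  invisible(df)
}

#' Export the per-node summary of a solution
#'
#' @inheritParams write_flux_table
#' @return Invisibly, the exported data frame
#'   (`node_id,G,L,X,residual`).
#' @export
write_node_summary <- function(solution, web, file) {
  ids <- node_ids(web)
  df <- data.frame(node_id = ids, G = solution$G, L = solution$L,
                   X = solution$X,
                   residual = solution$residuals[ids])
  rownames(df) <- NULL
  write_csv_commented(df, file)
  invisible(df)
}

#' Export the link-flux matrix (consumers in columns)
#'
#' @inheritParams write_flux_table
#' @return Invisibly, the matrix.
#' @export
write_flux_matrix <- function(solution, file) {
  df <- data.frame(resource_id = rownames(solution$F), solution$F,
                   check.names = FALSE)
  write_csv_commented(df, file)
  invisible(solution$F)
}

#' Export a function report
#'
#' @param report Data frame from [function_report()].
#' @param file Output CSV path.
#' @param web_id Identifier written in the first column.
#' @return Invisibly, the exported data frame.
#' @export
write_function_report <- function(report, file, web_id = "web") {
  df <- cbind(data.frame(web_id = web_id), report)
  write_csv_commented(df, file)
  invisible(df)
}

#' Read a run configuration
#'
#' A YAML key-value document declaring input paths (`nodes`, `links`,
#' `body_masses`, `efficiencies`, `regressions`), `temperature_C`, `units`,
#' `losses_per_unit_biomass`, `use_biomass_prefs`, `efficiency_level`,
#' `fmr_multiplier`, and `seed`. Missing keys take the package defaults.
#'
#' @param path YAML file path.
#' @return Named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(temperature_C = 20, losses_per_unit_biomass = TRUE,
                   use_biomass_prefs = TRUE, efficiency_level = "resource",
                   fmr_multiplier = 1, seed = 1, units = default_units())
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg
}

#' Write a machine-readable provenance block
#'
#' Records md5 hashes of every input file, the seed, and free-form parameters
#' so that a run can be audited and reproduced.
#'
#' @param path Output JSON path.
#' @param inputs Character vector of input file paths.
#' @param seed Integer seed used for the run.
#' @param params Named list of parameters worth recording.
#' @return Invisibly, the provenance list.
#' @export
write_provenance <- function(path, inputs = character(), seed = NA,
                             params = list()) {
  prov <- list(inputs = lapply(stats::setNames(inputs, basename(inputs)),
                               function(f) unname(tools::md5sum(f))),
               seed = seed, params = params,
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(prov)
}
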