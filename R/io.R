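#' @name io
#' @title Plain-text interfaces
#'
#' @description
#' All tables move as plain CSV and scenario configurations as JSON, so
#' every stage of the pipeline can be driven from the command line (see
#' `inst/cli/rstarcomp.R`) or from another language.
NULL

#' Write / read a long-format growth series table
#'
#' Columns: `strain, species, resource, level, replicate, day, rfu`.
#' @param data data.frame as produced by [gen_growth_series()].
#' @param path file path.
#' @export
write_growth_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_growth_csv
#' @export
read_growth_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "resource", "level", "replicate", "day", "rfu")
  assert_that(all(need %in% names(d)),
              "read_growth_csv: missing column(s): %s",
              paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' Write / read a community count table
#'
#' Columns: `week, mesocosm, treatment, taxon, count`.
#' @param data community data.frame.
#' @param path file path.
#' @export
write_community_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_community_csv
#' @export
read_community_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("week", "mesocosm", "treatment", "taxon", "count")
  assert_that(all(need %in% names(d)),
              "read_community_csv: missing column(s): %s",
              paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' Serialize / load a simulation scenario as JSON
#'
#' @param scenario a [sim_scenario()].
#' @param path file path.
#' @export
write_scenario_json <- function(scenario, path) {
  x <- unclass(scenario)
  # named kinetic vectors must serialize as JSON objects, not bare arrays
  x$species <- lapply(x$species, function(s) {
    for (f in c("mu_max", "Ks", "q")) s[[f]] <- as.list(s[[f]])
    s
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  species <- lapply(x$species, function(s) {
    s$mu_max <- unlist(s$mu_max); s$Ks <- unlist(s$Ks); s$q <- unlist(s$q)
    s
  })
  sim_scenario(species = species, resources = x$resources, m = x$m,
               horizon = x$horizon, rtol = x$rtol %||% 1e-8,
               atol = x$atol %||% 1e-10, out_dt = x$out_dt %||% 1)
}
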