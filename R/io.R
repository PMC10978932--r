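# On-disk formats: long/tidy CSV for tables and gridded fields (one value
# per row with explicit year/lat/lon), YAML for configuration, JSON for
# manifests and fitted parameters. Everything is plain text and
# deterministic so manifests of identical runs are identical.

#' Write a gridded field series as long-format CSV
#'
#' One row per (year, cell) with cell-centre coordinates; the variable name
#' and units travel in columns so files are self-describing.
#'
#' @param grids named list of matrices (names are years), or a single
#'   matrix (written with `year = NA`).
#' @param path output CSV path.
#' @param variable variable name (e.g. `"pm25"`).
#' @param units units string (e.g. `"ug/m3"`).
#' @param lat,lon cell-centre coordinate vectors.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grids, path, variable, units, lat, lon) {
  if (is.matrix(grids)) grids <- stats::setNames(list(grids), "")
  yrs <- names(grids)
  rows <- lapply(seq_along(grids), function(i) {
    m <- grids[[i]]
    data.frame(year = if (nzchar(yrs[i])) as.integer(yrs[i]) else NA_integer_,
               lat = lat[row(m)], lon = lon[col(m)],
               variable = variable, units = units, value = as.numeric(m))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format grid CSV back into matrices
#'
#' @param path CSV written by [write_grid_csv()].
#' @return Named list of matrices (names are years) with `lat`, `lon` and
#'   `units` attributes.
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  out <- lapply(split(df, factor(df$year, exclude = NULL)), function(d) {
    m <- matrix(NA_real_, length(lat), length(lon))
    m[cbind(match(d$lat, lat), match(d$lon, lon))] <- d$value
    m
  })
  attr(out, "lat") <- lat; attr(out, "lon") <- lon
  attr(out, "units") <- df$units[1]
  out
}

world_config_as_list <- function(config) {
  list(n_countries = config$n_countries, grid_shape = config$grid_shape,
       cell_degrees = config$cell_degrees, years = range(config$years),
       base_year = config$base_year, n_models = config$n_models,
       scenarios = config$scenarios, seed = config$seed,
       total_population = config$total_population,
       share65_2015 = config$share65_2015, hist = config$hist,
       noise = config$noise,
       scenario_params = as.list(config$scenario_params))
}

#' Write a synthetic world to a directory
#'
#' Emits the configuration (YAML), country tables (CSV), grids (long CSV),
#' ground-truth parameters (JSON) and a deterministic manifest.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if needed).
#' @param include_fields also write the per-scenario/model aerosol
#'   component grids (large; default `FALSE`).
#' @return The manifest, invisibly.
#' @export
write_world <- function(world, dir, include_fields = FALSE) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  yaml::write_yaml(world_config_as_list(world$config), p("config.yaml"),
                   precision = 15L)
  utils::write.csv(world$sdi, p("sdi.csv"), row.names = FALSE)
  utils::write.csv(world$age_fractions, p("age_fractions.csv"),
                   row.names = FALSE)
  pop <- do.call(rbind, lapply(names(world$pop_totals), function(sc) {
    m <- world$pop_totals[[sc]]
    data.frame(scenario = sc, year = as.integer(rownames(m))[row(m)],
               country = colnames(m)[col(m)], population = as.numeric(m))
  }))
  utils::write.csv(pop, p("population.csv"), row.names = FALSE)
  w <- do.call(rbind, lapply(seq_along(world$countries), function(l)
    data.frame(country = world$countries[l], cell = world$country_cells[[l]],
               weight = world$pop_weights[[l]])))
  utils::write.csv(w, p("pop_weights.csv"), row.names = FALSE)
  write_grid_csv(world$country_mask, p("country_mask.csv"),
                 "country_index", "1", world$lat, world$lon)
  write_grid_csv(world$observed_pm25_base, p("observed_pm25_base.csv"),
                 "pm25", "ug/m3", world$lat, world$lon)
  tp <- world$truth_mortality_params
  jsonlite::write_json(list(
    schema_version = 1L, beta1 = tp$beta1, beta2 = tp$beta2,
    theta = list(age_group = rownames(tp$theta),
                 disease = colnames(tp$theta), value = tp$theta),
    alpha = tp$alpha, ln_r = tp$ln_r, sigma = tp$sigma, knot = tp$knot,
    t_ref = tp$t_ref), p("truth_params.json"),
    auto_unbox = TRUE, digits = NA)
  if (include_fields) {
    for (sc in names(world$aerosol_fields)) {
      for (m in names(world$aerosol_fields[[sc]])) {
        per_year <- world$aerosol_fields[[sc]][[m]]
        for (v in c("bc", "oa", "so4", "ss", "dust")) {
          grids <- lapply(per_year, `[[`, v)
          write_grid_csv(grids, p(sprintf("aerosol_%s_%s_%s.csv", sc, m, v)),
                         v, "ug/m3", world$lat, world$lon)
        }
      }
    }
  }
  invisible(write_manifest(dir))
}

#' Read a synthetic world from a directory
#'
#' Reconstructs the world from [write_world()] output by regenerating from
#' the stored configuration (the generator is deterministic given the
#' seed), then verifying the stored observed base grid matches.
#'
#' @param dir directory written by [write_world()].
#' @return A `synthetic_world`.
#' @export
read_world <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  sp <- as.data.frame(cfg$scenario_params, stringsAsFactors = FALSE)
  config <- world_config(
    n_countries = cfg$n_countries, grid_shape = unlist(cfg$grid_shape),
    cell_degrees = cfg$cell_degrees,
    years = cfg$years[1]:cfg$years[2], base_year = cfg$base_year,
    n_models = cfg$n_models, scenarios = unlist(cfg$scenarios),
    seed = cfg$seed, scenario_params = sp,
    total_population = cfg$total_population,
    share65_2015 = cfg$share65_2015,
    hist = lapply(cfg$hist, unlist), noise = cfg$noise)
  world <- generate_world(config)
  obs <- read_grid_csv(file.path(dir, "observed_pm25_base.csv"))[[1]]
  if (max(abs(obs - world$observed_pm25_base)) > 1e-6)
    abort("read_world: stored observations do not match the regenerated world")
  world
}

md5_of_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Deterministic run manifest for a directory
#'
#' Records the package version and an md5 checksum per file; identical
#' configurations and inputs yield identical manifests.
#'
#' @param dir directory to fingerprint.
#' @param path output JSON path, default `manifest.json` inside `dir`.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(dir, path = file.path(dir, "manifest.json")) {
  files <- sort(setdiff(list.files(dir, recursive = TRUE),
                        basename(path)))
  sums <- tools::md5sum(file.path(dir, files))
  manifest <- list(
    package = "pm25burden",
    version = as.character(utils::packageVersion("pm25burden")),
    files = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write projection result tables to a directory
#'
#' Long-format CSVs: totals (`scope, scope_id, year, scenario, band,
#' deaths`), per-country mid totals, and 65+ death shares.
#'
#' @param proj a [run_projection()] result.
#' @param dir output directory.
#' @return The manifest, invisibly.
#' @export
write_projection <- function(proj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tot <- data.frame(scope = "global", scope_id = "global",
                    year = proj$totals$year, scenario = proj$totals$scenario,
                    band = proj$totals$band, deaths = proj$totals$deaths)
  utils::write.csv(tot, file.path(dir, "dapp_totals.csv"), row.names = FALSE)
  utils::write.csv(proj$country, file.path(dir, "dapp_country.csv"),
                   row.names = FALSE)
  utils::write.csv(proj$age_shares, file.path(dir, "age_shares.csv"),
                   row.names = FALSE)
  if (!is.null(proj$jensen))
    utils::write.csv(proj$jensen, file.path(dir, "ensemble_paths.csv"),
                     row.names = FALSE)
  invisible(write_manifest(dir))
}
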