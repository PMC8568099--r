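# Serialization: world tables as UTF-8 CSV with a YAML metadata echo,
# adapter readers for externally supplied tables, and event-log export.

#' Write a world to a directory
#'
#' Writes `agents.csv`, `places.csv`, `resources.csv` (header row, ids as
#' strings) and `world_meta.yaml` (seed, frame, config echo).
#' @param world a `crx_world`
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as_str <- function(dt, cols) {
    dt <- copy(dt)
    for (cc in intersect(cols, names(dt)))
      dt[, (cc) := as.character(get(cc))]
    dt
  }
  data.table::fwrite(as_str(world$agents,
                            c("agent_id", "household_id", "workplace_id",
                              "school_id")),
                     file.path(dir, "agents.csv"))
  data.table::fwrite(as_str(world$places, "place_id"),
                     file.path(dir, "places.csv"))
  data.table::fwrite(as_str(world$resources, c("resource_id", "place_id")),
                     file.path(dir, "resources.csv"))
  meta <- list(seed = world$seed, frame = world$frame,
               bounding_box = world$bounding_box,
               n_agents = nrow(world$agents),
               config = lapply(unclass(world$config), function(v)
                 if (is.numeric(v) || is.character(v)) as.vector(v) else v))
  yaml::write_yaml(meta, file.path(dir, "world_meta.yaml"))
  invisible(dir)
}

#' Read a world from a directory (adapter)
#'
#' Accepts externally supplied tables with the `agents.csv` /
#' `places.csv` / `resources.csv` schemas; ids are coerced to integers
#' and referential integrity is validated.
#' @param dir directory containing the CSV tables (and optionally
#'   `world_meta.yaml`)
#' @return a `crx_world`
#' @export
read_world <- function(dir) {
  agents <- data.table::fread(file.path(dir, "agents.csv"))
  places <- data.table::fread(file.path(dir, "places.csv"))
  resources <- data.table::fread(file.path(dir, "resources.csv"))
  for (cc in c("agent_id", "household_id", "workplace_id", "school_id"))
    if (cc %in% names(agents)) agents[, (cc) := as.integer(get(cc))]
  places[, place_id := as.integer(place_id)]
  for (cc in c("resource_id", "place_id"))
    resources[, (cc) := as.integer(get(cc))]
  meta_path <- file.path(dir, "world_meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  world <- structure(list(
    agents = agents, places = places, resources = resources,
    frame = meta$frame %||% "planar_km",
    bounding_box = unlist(meta$bounding_box %||%
                            c(min(places$x), min(places$y),
                              max(places$x), max(places$y))),
    seed = meta$seed %||% NA_integer_, config = meta$config),
    class = "crx_world")
  validate_world(world)
  world
}

#' Write run event logs and metadata to a directory
#'
#' CSV event tables (`events_dosing.csv`, `events_exchange.csv`,
#' `events_use.csv`, `events_visit.csv`, `healtherx_log.csv`), weekly
#' knowledge snapshot CSVs and a `run_meta.yaml` echo.
#' @param run a `crx_run`
#' @param dir output directory
#' @return invisibly, the directory
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(run$events$dosing, file.path(dir, "events_dosing.csv"))
  data.table::fwrite(run$events$exchange, file.path(dir, "events_exchange.csv"))
  data.table::fwrite(run$events$use, file.path(dir, "events_use.csv"))
  data.table::fwrite(run$events$visit, file.path(dir, "events_visit.csv"))
  data.table::fwrite(run$healtherx, file.path(dir, "healtherx_log.csv"))
  for (wk in names(run$snapshots))
    data.table::fwrite(run$snapshots[[wk]],
                       file.path(dir, sprintf("knowledge_week%s.csv", wk)))
  yaml::write_yaml(run$meta, file.path(dir, "run_meta.yaml"))
  invisible(dir)
}
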