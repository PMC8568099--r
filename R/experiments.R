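# Experiment pipelines: clinical-versus-social dosing reach, delivery-mode
# comparison, and information-sharing-propensity sweeps, with burn-in
# handling, replicates and summary outputs.

#' An experiment plan
#'
#' Bundles the world/schedule configurations, a base simulation
#' configuration, a replicate count and the measurement window. The world
#' and schedule pool are generated once per plan; each replicate runs the
#' simulation with a distinct derived seed.
#'
#' @param world_config [demographic_config()]
#' @param schedule_cfg [schedule_config()]
#' @param sim_config [simulation_config()]
#' @param replicates number of runs (>= 1)
#' @param week measurement week (default 3, the first post-burn-in week)
#' @param seed base seed for world, pool and replicate derivation
#' @param catalog condition catalog
#' @return `crx_experiment_plan` list
#' @export
experiment_plan <- function(world_config = demographic_config(),
                            schedule_cfg = schedule_config(),
                            sim_config = simulation_config(),
                            replicates = 5L, week = 3L, seed = 1L,
                            catalog = condition_catalog_default()) {
  if (replicates < 1L) abort_config("replicates must be >= 1")
  if (week * 7L > sim_config$n_days)
    abort_config("measurement week lies beyond the run horizon")
  structure(list(world_config = world_config, schedule_cfg = schedule_cfg,
                 sim_config = sim_config, replicates = as.integer(replicates),
                 week = as.integer(week), seed = as.integer(seed),
                 catalog = catalog),
            class = "crx_experiment_plan")
}

plan_world <- function(plan) {
  world <- generate_world(plan$world_config, seed = derive_seed(plan$seed, 0L))
  world$agents <- assign_conditions(world$agents, plan$catalog)
  pool <- build_synthetic_pool(plan$schedule_cfg, plan$world_config,
                               seed = derive_seed(plan$seed, 1L))
  list(world = world, pool = pool)
}

plan_run <- function(plan, env, replicate, override = list()) {
  cfg <- plan$sim_config
  cfg$seed <- derive_seed(plan$seed, 100L + replicate)
  for (nm in names(override)) cfg[[nm]] <- override[[nm]]
  run_simulation(env$world, env$pool, cfg, catalog = plan$catalog)
}

#' Classify clinical versus social-only retainers
#'
#' "Retained" means: the entry is present in the agent's capped store at
#' the end of the measurement week (eviction is forgetting), carries the
#' HealtheRx-provenance flag, and has beta at or above `beta_floor`.
#' Clinically dosed agents are those with at least one HealtheRx issued up
#' to the window end; the social-only set are rx-derived retainers never
#' clinically dosed. The two sets are disjoint by construction. Both
#' denominators discussed for the reach ratio are reported:
#' `n_clinical` (clinically dosed AND retaining) and `n_clinical_dosed`
#' (clinically dosed regardless of retention); `ratio` uses the former.
#'
#' @param run a `crx_run` with a snapshot for `week`
#' @param week measurement week (default 3)
#' @param beta_floor minimum beta for "retained" (default 0, i.e. store
#'   membership)
#' @return one-row data.table: `n_clinical`, `n_clinical_dosed`,
#'   `n_social_only`, `ratio`, `ratio_dosed`
#' @export
classify_retainers <- function(run, week = 3L, beta_floor = 0) {
  snap <- run$snapshots[[as.character(week)]]
  if (is.null(snap))
    abort_config("run has no knowledge snapshot for week %d", week)
  h_end <- week * 168L
  rx_agents <- unique(run$healtherx[hour < h_end, agent_id])
  retainers <- unique(snap[rx_derived == TRUE & beta >= beta_floor, agent_id])
  n_clin <- length(intersect(rx_agents, retainers))
  n_social <- length(setdiff(retainers, rx_agents))
  data.table(n_clinical = n_clin,
             n_clinical_dosed = length(rx_agents),
             n_social_only = n_social,
             ratio = if (n_clin > 0L) n_social / n_clin else NA_real_,
             ratio_dosed = if (length(rx_agents) > 0L)
               n_social / length(rx_agents) else NA_real_)
}

#' Clinical-versus-social dosing reach experiment
#'
#' One run per replicate (distinct seeds) on a shared world and schedule
#' pool; per-run retainer classification plus the mean and range of the
#' social-to-clinical reach ratio.
#'
#' @param plan an [experiment_plan()]
#' @return list with `results` (one row per run) and `summary`
#' @export
dosing_reach_experiment <- function(plan) {
  env <- plan_world(plan)
  rows <- vector("list", plan$replicates)
  for (r in seq_len(plan$replicates)) {
    run <- plan_run(plan, env, r)
    cls <- classify_retainers(run, plan$week)
    rows[[r]] <- cbind(data.table(replicate = r, seed = run$meta$seed), cls)
  }
  results <- data.table::rbindlist(rows)
  summary <- data.table(
    mean_ratio = mean(results$ratio, na.rm = TRUE),
    min_ratio = suppressWarnings(min(results$ratio, na.rm = TRUE)),
    max_ratio = suppressWarnings(max(results$ratio, na.rm = TRUE)),
    mean_n_clinical = mean(results$n_clinical),
    mean_n_social_only = mean(results$n_social_only))
  list(results = results, summary = summary, world = env$world)
}

#' Delivery-mode experiment
#'
#' Replicated runs for each HealtheRx delivery mode (physician, nurse,
#' clerk) with matched seeds across modes; per-mode means and SDs of the
#' social-only reach plus a descriptive Kruskal-Wallis rank test of mode
#' differences.
#'
#' @param plan an [experiment_plan()]
#' @param modes subset of `c("physician", "nurse", "clerk")`
#' @return list with `results`, `by_mode`, and `kruskal` (htest or NULL)
#' @export
delivery_mode_experiment <- function(plan,
                                     modes = c("physician", "nurse", "clerk")) {
  stopifnot(all(modes %in% c("physician", "nurse", "clerk")))
  env <- plan_world(plan)
  rows <- list()
  for (mode in modes) {
    for (r in seq_len(plan$replicates)) {
      run <- plan_run(plan, env, r,
                      override = list(delivery = delivery_config(mode)))
      cls <- classify_retainers(run, plan$week)
      rows[[length(rows) + 1L]] <-
        cbind(data.table(delivery_mode = mode, replicate = r,
                         seed = run$meta$seed), cls)
    }
  }
  results <- data.table::rbindlist(rows)
  by_mode <- results[, .(mean_n_social_only = mean(n_social_only),
                         sd_n_social_only = stats::sd(n_social_only),
                         mean_ratio = mean(ratio, na.rm = TRUE)),
                     by = delivery_mode]
  kw <- if (length(modes) > 1L && plan$replicates > 1L)
    kruskal.test(results$n_social_only, factor(results$delivery_mode))
  else NULL
  list(results = results, by_mode = by_mode, kruskal = kw)
}

#' Information-sharing propensity sweep
#'
#' Runs the simulation at each p-rate multiplier level (matched seeds
#' across levels), builds the measurement-week diffusion network of each
#' run and summarizes its degree structure.
#'
#' @param plan an [experiment_plan()]
#' @param multipliers named ordered multipliers on the low/medium/high
#'   rates (default `c(low = 0.5, medium = 1, high = 2)`)
#' @return list with `by_level` (mean network summaries per level),
#'   `results` (per run) and `distributions` (degree distributions)
#' @export
pscore_sweep <- function(plan, multipliers = c(low = 0.5, medium = 1, high = 2)) {
  stopifnot(all(multipliers >= 0))
  env <- plan_world(plan)
  window <- c((plan$week - 1L) * 168, plan$week * 168)
  rows <- list(); dists <- list()
  for (lev in names(multipliers)) {
    for (r in seq_len(plan$replicates)) {
      run <- plan_run(plan, env, r,
                      override = list(p_rate_multiplier = multipliers[[lev]]))
      net <- build_network(run$events$exchange, window)
      sm <- network_summary(net)
      rows[[length(rows) + 1L]] <-
        cbind(data.table(level = lev, multiplier = multipliers[[lev]],
                         replicate = r), sm)
      dists[[length(dists) + 1L]] <-
        cbind(data.table(level = lev, replicate = r), degree_distribution(net))
    }
  }
  results <- data.table::rbindlist(rows)
  by_level <- results[, .(mean_degree = mean(ifelse(is.na(mean_degree), 0,
                                                    mean_degree)),
                          max_degree = max(c(0L, max_degree), na.rm = TRUE),
                          mean_edges = mean(n_edges)),
                      by = .(level, multiplier)]
  list(by_level = by_level, results = results,
       distributions = data.table::rbindlist(dists))
}

#' Export home locations of clinical versus social-only retainers
#'
#' Writes two point sets (CSV and GeoJSON) with the household coordinates
#' of agents who retained HealtheRx-derived information from clinical
#' versus exclusively social dosing, for external mapping.
#'
#' @param run a `crx_run`
#' @param world the `crx_world` the run used
#' @param dir output directory
#' @param week measurement week
#' @return invisibly, a named list of written paths
#' @export
export_geography <- function(run, world, dir, week = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  snap <- run$snapshots[[as.character(week)]]
  if (is.null(snap)) abort_config("run has no snapshot for week %d", week)
  h_end <- week * 168L
  rx_agents <- unique(run$healtherx[hour < h_end, agent_id])
  retainers <- unique(snap[rx_derived == TRUE, agent_id])
  sets <- list(clinical = intersect(rx_agents, retainers),
               social_only = setdiff(retainers, rx_agents))
  paths <- list()
  for (nm in names(sets)) {
    ids <- sets[[nm]]
    hh <- world$agents[agent_id %in% ids,
                       .(agent_id, household_id)]
    pl <- world$places[match(hh$household_id, world$places$place_id)]
    pts <- data.table(agent_id = hh$agent_id, x = pl$x, y = pl$y)
    csv <- file.path(dir, paste0(nm, "_retainers.csv"))
    data.table::fwrite(pts, csv)
    gj <- file.path(dir, paste0(nm, "_retainers.geojson"))
    write_geojson_points(pts, gj)
    paths[[nm]] <- c(csv = csv, geojson = gj)
  }
  invisible(paths)
}

write_geojson_points <- function(pts, path) {
  features <- lapply(seq_len(nrow(pts)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(pts$x[i], pts$y[i])),
         properties = list(agent_id = pts$agent_id[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Beta trajectory of tracked (agent, resource) pairs
#'
#' Requires the run to have been configured with `track` pairs; returns
#' the hourly decayed-beta series for one pair, suitable for plotting the
#' characteristic jump-at-dose / decline-between-doses shape.
#' @param run a `crx_run`
#' @param agent_id,resource_id the tracked pair
#' @return data.table (`hour`, `beta`)
#' @export
beta_trajectory <- function(run, agent_id, resource_id) {
  tr <- run$trajectories
  if (is.null(tr)) abort_config("run was not configured with tracked pairs")
  j <- which(tr$pairs$agent_id == agent_id &
               tr$pairs$resource_id == resource_id)
  if (length(j) != 1L) abort_config("pair not tracked")
  data.table(hour = seq_len(nrow(tr$beta)) - 1L, beta = tr$beta[, j])
}
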