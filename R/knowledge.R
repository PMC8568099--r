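# Per-agent resource-knowledge dynamics: source-dependent reinforcement
# (beta-score boosting), decay, distance-stratified initial seeding, and
# capped stores with minimum-beta eviction.

#' Default dose-source table
#'
#' Source-specific exponents epsilon used by the knowledge update: smaller
#' epsilon means a stronger boost. Defaults: Doctor 0.05, Nurse 0.15,
#' ClinicalStaff 0.25, Use 0.2, Peer 0.9, None 1.
#' @return named numeric vector of epsilon values in (0, 1]
#' @export
dose_sources <- function() {
  c(Doctor = 0.05, Nurse = 0.15, ClinicalStaff = 0.25,
    Use = 0.2, Peer = 0.9, None = 1)
}

#' Knowledge dynamics parameters
#'
#' @param lambda decay parameter, constrained to the allowable range
#'   \[0.991, 0.9994\]
#' @param sources named epsilon table (see [dose_sources()]); all values
#'   must lie in (0, 1]
#' @param capacity maximum number of resources an agent can hold knowledge
#'   about (default 200)
#' @param decay_mode `"geometric"` (default; beta shrinks by `lambda` per
#'   idle hour) or `"as_printed"` (hourly application of the update rule
#'   with the `None` source, which *increases* beta; retained for fidelity
#'   experiments)
#' @param beta_init entry value for a resource first learned through a
#'   dose; the update rule has a fixed point at beta = 0, so new knowledge
#'   must start above it (default 0.1)
#' @return `crx_knowledge_params` list
#' @export
knowledge_params <- function(lambda = 0.991, sources = dose_sources(),
                             capacity = 200L,
                             decay_mode = c("geometric", "as_printed"),
                             beta_init = 0.1) {
  decay_mode <- match.arg(decay_mode)
  if (lambda < 0.991 || lambda > 0.9994)
    abort_config("lambda must lie in [0.991, 0.9994]")
  if (any(sources <= 0) || any(sources > 1))
    abort_config("all source epsilon values must lie in (0, 1]")
  if (capacity < 1L) abort_config("capacity must be >= 1")
  structure(list(lambda = lambda, sources = sources,
                 capacity = as.integer(capacity), decay_mode = decay_mode,
                 beta_init = beta_init),
            class = "crx_knowledge_params")
}

#' Boost a knowledge score by an information dose
#'
#' The score evolves as `beta' = lambda * beta^epsilon * (1 - beta) + beta`
#' where `epsilon` depends on the information source. The update is
#' monotone non-decreasing with fixed points at 0 and 1, and stronger for
#' sources with smaller epsilon (Doctor > Nurse > Use > ClinicalStaff >
#' Peer).
#'
#' @param beta current score(s) in \[0, 1\] (vectorized)
#' @param source one of `names(params$sources)`
#' @param params [knowledge_params()]
#' @return boosted score(s) in \[0, 1\]
#' @export
boost <- function(beta, source, params = knowledge_params()) {
  if (!source %in% names(params$sources))
    abort_config("unknown dose source '%s'", source)
  if (any(beta < 0 | beta > 1)) abort_config("beta must lie in [0, 1]")
  eps <- params$sources[[source]]
  params$lambda * beta^eps * (1 - beta) + beta
}

#' Decay a knowledge score over idle hours
#'
#' Geometric mode multiplies by `lambda` once per hour (strictly decreasing
#' for beta > 0); `as_printed` mode applies the boost rule with the `None`
#' source once per hour, reproducing the printed functional form verbatim
#' (which grows rather than decays).
#'
#' @param beta current score(s) in \[0, 1\]
#' @param dt_hours idle hours (>= 0)
#' @param params [knowledge_params()]
#' @return decayed score(s)
#' @export
decay_beta <- function(beta, dt_hours, params = knowledge_params()) {
  stopifnot(all(dt_hours >= 0))
  if (params$decay_mode == "geometric") {
    beta * params$lambda^dt_hours
  } else {
    for (i in seq_len(max(dt_hours))) {
      upd <- dt_hours >= i
      beta[upd] <- boost(beta[upd], "None", params)
    }
    beta
  }
}

#' Seeding parameters for initial resource knowledge
#'
#' Agents start out knowing 10--100 resources within a low-distance radius
#' of home (1 mile = 1.609 km), 1--5 at medium distance (1--3 miles) and
#' 1--5 beyond, with initial scores drawn uniformly from `init_beta_range`.
#'
#' @param low_radius_km,mid_radius_km stratum radii (strictly increasing)
#' @param low_count_range,mid_count_range,far_count_range inclusive integer
#'   ranges for per-stratum seed counts
#' @param init_beta_range uniform range for seeded beta values
#' @return `crx_seeding_params` list
#' @export
seeding_params <- function(low_radius_km = 1.609, mid_radius_km = 4.83,
                           low_count_range = c(10L, 100L),
                           mid_count_range = c(1L, 5L),
                           far_count_range = c(1L, 5L),
                           init_beta_range = c(0.1, 0.5)) {
  if (!(low_radius_km < mid_radius_km))
    abort_config("radii must be strictly increasing")
  for (r in list(low_count_range, mid_count_range, far_count_range))
    if (r[1] > r[2]) abort_config("count range must have min <= max")
  structure(list(low_radius_km = low_radius_km, mid_radius_km = mid_radius_km,
                 low_count_range = as.integer(low_count_range),
                 mid_count_range = as.integer(mid_count_range),
                 far_count_range = as.integer(far_count_range),
                 init_beta_range = init_beta_range),
            class = "crx_seeding_params")
}

## one stratum draw: a count from [rng], then that many resource ids without
## replacement (clipped to the stratum size), then one uniform beta each
.seed_stratum <- function(ids, rng, betas) {
  k <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
  k <- min(k, length(ids))
  picked <- ids[sample.int(length(ids), k)]
  list(ids = picked, beta = runif(k, betas[1], betas[2]))
}

#' Seed one agent's knowledge store
#'
#' Distance-stratified random assignment around the agent's household: the
#' per-stratum counts are drawn uniformly from the configured ranges and
#' clipped to the number of resources available in the stratum. Empty
#' strata yield zero seeds. Draw order (for reproducibility): low count,
#' low ids, low betas, then mid, then far.
#'
#' @param agent one-row agent table
#' @param world a `crx_world`
#' @param sp [seeding_params()]
#' @param params [knowledge_params()]
#' @return a knowledge store data.table (`resource_id`, `beta`,
#'   `last_update`, `rx_derived`), at most `capacity` rows
#' @export
seed_knowledge <- function(agent, world, sp = seeding_params(),
                           params = knowledge_params()) {
  res <- world$resources
  if (nrow(res) == 0L) return(knowledge_store())
  home <- world$places[match(agent$household_id, world$places$place_id)]
  pl <- world$places[match(res$place_id, world$places$place_id)]
  d <- coord_distance(home$x, home$y, pl$x, pl$y, world$frame)
  low <- .seed_stratum(res$resource_id[d <= sp$low_radius_km],
                       sp$low_count_range, sp$init_beta_range)
  mid <- .seed_stratum(res$resource_id[d > sp$low_radius_km & d <= sp$mid_radius_km],
                       sp$mid_count_range, sp$init_beta_range)
  far <- .seed_stratum(res$resource_id[d > sp$mid_radius_km],
                       sp$far_count_range, sp$init_beta_range)
  st <- data.table(resource_id = c(low$ids, mid$ids, far$ids),
                   beta = c(low$beta, mid$beta, far$beta),
                   last_update = 0L, rx_derived = FALSE)
  setkey(st, resource_id)
  if (nrow(st) > params$capacity)
    st <- st[order(-beta, resource_id)][seq_len(params$capacity)][order(resource_id)]
  st[]
}

#' An empty knowledge store
#' @return zero-row store data.table
#' @export
knowledge_store <- function() {
  data.table(resource_id = integer(), beta = numeric(),
             last_update = integer(), rx_derived = logical())
}

#' Seed knowledge for every agent of a world
#'
#' Calls the per-agent seeding in increasing `agent_id` order (one RNG
#' stream), returning a single keyed table.
#' @inheritParams seed_knowledge
#' @param world a `crx_world`
#' @return data.table (`agent_id`, `resource_id`, `beta`, `last_update`,
#'   `rx_derived`), keyed by agent and resource
#' @export
seed_world_knowledge <- function(world, sp = seeding_params(),
                                 params = knowledge_params()) {
  agents <- world$agents
  res <- world$resources
  if (nrow(agents) == 0L || nrow(res) == 0L) {
    kn <- data.table(agent_id = integer(), resource_id = integer(),
                     beta = numeric(), last_update = integer(),
                     rx_derived = logical())
    setkey(kn, agent_id, resource_id)
    return(kn)
  }
  pl <- world$places[match(res$place_id, world$places$place_id)]
  hx <- world$places$x[match(agents$household_id, world$places$place_id)]
  hy <- world$places$y[match(agents$household_id, world$places$place_id)]
  out <- vector("list", nrow(agents))
  for (i in seq_len(nrow(agents))) {
    d <- coord_distance(hx[i], hy[i], pl$x, pl$y, world$frame)
    low <- .seed_stratum(res$resource_id[d <= sp$low_radius_km],
                         sp$low_count_range, sp$init_beta_range)
    mid <- .seed_stratum(res$resource_id[d > sp$low_radius_km & d <= sp$mid_radius_km],
                         sp$mid_count_range, sp$init_beta_range)
    far <- .seed_stratum(res$resource_id[d > sp$mid_radius_km],
                         sp$far_count_range, sp$init_beta_range)
    out[[i]] <- data.table(agent_id = agents$agent_id[i],
                           resource_id = c(low$ids, mid$ids, far$ids),
                           beta = c(low$beta, mid$beta, far$beta))
  }
  kn <- data.table::rbindlist(out)
  kn[, `:=`(last_update = 0L, rx_derived = FALSE)]
  setkey(kn, agent_id, resource_id)
  kn[]
}

#' Insert or update one entry of a knowledge store
#'
#' Existing entries have their beta replaced and the HealtheRx-provenance
#' flag ORed. A new entry is inserted when there is free capacity;
#' at capacity it is inserted only if its beta exceeds the current minimum,
#' which is then evicted (ties on beta broken by lower `resource_id`
#' evicted first). The store never exceeds `params$capacity` rows.
#'
#' @param store a knowledge store data.table
#' @param resource_id integer resource id
#' @param new_beta replacement/initial beta in \[0, 1\]
#' @param rx_flag logical: dose traces to a HealtheRx
#' @param params [knowledge_params()]
#' @param t hour index recorded in `last_update`
#' @return list with the updated `store` and `evicted` (resource id or NULL)
#' @export
upsert <- function(store, resource_id, new_beta, rx_flag = FALSE,
                   params = knowledge_params(), t = 0L) {
  stopifnot(new_beta >= 0, new_beta <= 1)
  evicted <- NULL
  i <- match(resource_id, store$resource_id)
  if (!is.na(i)) {
    store[i, `:=`(beta = new_beta, last_update = as.integer(t),
                  rx_derived = rx_derived | rx_flag)]
  } else if (nrow(store) < params$capacity) {
    store <- rbind(store, data.table(resource_id = as.integer(resource_id),
                                     beta = new_beta,
                                     last_update = as.integer(t),
                                     rx_derived = rx_flag))
    setkey(store, resource_id)
  } else {
    jmin <- store[order(beta, resource_id), resource_id][1]
    bmin <- store[resource_id == jmin, beta]
    if (new_beta > bmin) {
      evicted <- jmin
      store <- store[resource_id != jmin]
      store <- rbind(store, data.table(resource_id = as.integer(resource_id),
                                       beta = new_beta,
                                       last_update = as.integer(t),
                                       rx_derived = rx_flag))
      setkey(store, resource_id)
    }
  }
  list(store = store, evicted = evicted)
}

#' Export a knowledge table (or snapshot) to CSV
#' @param kn knowledge table with an `agent_id` column
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_knowledge <- function(kn, path) {
  data.table::fwrite(kn, path)
  invisible(path)
}
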