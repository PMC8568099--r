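# The hourly time-stepped simulation: daily schedule draws, movement and
# co-location, clinic-visit dosing, peer information exchange, A/B
# resource-use decisions, lazy decay and event logging.

#' Decision parameters for the A/B resource-use choice
#'
#' A known resource j is used by agent i when
#' `beta_ij * delta_ij * gamma_j > alpha_i`, where `delta = exp(-d / d0)`
#' is a decreasing distance factor in (0, 1], `gamma_j` the resource's
#' inertia and `alpha_i` the agent's activation threshold. The printed
#' multiplicative form of the decision rule would reward distance; the
#' exponential transform implements distance as effort.
#'
#' @param d0_km distance scale of the exponential transform (default 2 km)
#' @return `crx_decision_params` list
#' @export
decision_params <- function(d0_km = 2.0) {
  if (d0_km <= 0) abort_config("d0_km must be positive")
  structure(list(d0_km = d0_km), class = "crx_decision_params")
}

#' Simulation configuration
#'
#' @param n_days simulated days (default 28; must exceed `burn_in_days`)
#' @param burn_in_days days flagged as burn-in in the logs (default 14);
#'   burn-in events are flagged, never dropped
#' @param seed integer seed; the single RNG stream for the whole run
#' @param knowledge [knowledge_params()]
#' @param seeding [seeding_params()]
#' @param delivery [delivery_config()]
#' @param decision [decision_params()]
#' @param p_rates optional override of the pool's propensity rates
#' @param p_rate_multiplier scalar multiplier on the low/medium/high rates
#'   (results clipped to \[0, 1\]); used by propensity sweeps
#' @param contacts_per_agent_hour cap `m` on potential givers sampled per
#'   receiver-hour (default 10)
#' @param shares_per_exchange resources transmitted per fired exchange
#'   (default 1)
#' @param share_policy `"top_beta"` (giver transmits their highest-beta
#'   resources) or `"beta_weighted"` (sampled proportional to beta)
#' @param out_of_home_radius_km radius of the uniform out-of-home draw
#'   around the household (default 5 km)
#' @param log_movement record an (hour, agent, place) row per agent-hour
#'   (memory-heavy; default FALSE)
#' @param track optional data.frame of (agent_id, resource_id) pairs whose
#'   beta trajectories are recorded every hour
#' @param initial_knowledge optional pre-seeded knowledge table (as from
#'   [seed_world_knowledge()]); when NULL the run seeds knowledge itself
#'   from its own stream
#' @return `crx_simulation_config` list
#' @export
simulation_config <- function(n_days = 28L, burn_in_days = 14L, seed = 1L,
                              knowledge = knowledge_params(),
                              seeding = seeding_params(),
                              delivery = delivery_config(),
                              decision = decision_params(),
                              p_rates = NULL,
                              p_rate_multiplier = 1,
                              contacts_per_agent_hour = 10L,
                              shares_per_exchange = 1L,
                              share_policy = c("top_beta", "beta_weighted"),
                              out_of_home_radius_km = 5,
                              log_movement = FALSE,
                              track = NULL,
                              initial_knowledge = NULL) {
  share_policy <- match.arg(share_policy)
  if (n_days <= burn_in_days)
    abort_config("n_days must exceed burn_in_days")
  if (contacts_per_agent_hour < 1L) abort_config("contact cap m must be >= 1")
  if (shares_per_exchange < 1L) abort_config("shares_per_exchange must be >= 1")
  structure(list(n_days = as.integer(n_days),
                 burn_in_days = as.integer(burn_in_days),
                 seed = as.integer(seed),
                 knowledge = knowledge, seeding = seeding,
                 delivery = delivery, decision = decision,
                 p_rates = p_rates, p_rate_multiplier = p_rate_multiplier,
                 contacts_per_agent_hour = as.integer(contacts_per_agent_hour),
                 shares_per_exchange = as.integer(shares_per_exchange),
                 share_policy = share_policy,
                 out_of_home_radius_km = out_of_home_radius_km,
                 log_movement = isTRUE(log_movement),
                 track = track,
                 initial_knowledge = initial_knowledge),
            class = "crx_simulation_config")
}

#' Resolve the location of one agent for one activity
#'
#' `home`/`work`/`school` map to the agent's anchors (work and school fall
#' back to home when unassigned); `out_of_home` is a uniform draw among
#' non-household places within `radius_km` of the agent's household (the
#' nearest non-household place when none is in radius); `service_site`
#' resolves to the place of the nearest resource providing one of the
#' activity's mapped services (A/B activities are instead resolved by
#' [decide_ab()] inside the engine).
#'
#' @param agent one-row agent table
#' @param activity one-row catalog entry
#' @param world a `crx_world`
#' @param radius_km out-of-home radius
#' @return a place id
#' @export
assign_location <- function(agent, activity, world, radius_km = 5) {
  pol <- activity$location_policy
  home <- agent$household_id
  if (pol == "home") return(home)
  if (pol == "work") return(if (is.na(agent$workplace_id)) home else agent$workplace_id)
  if (pol == "school") return(if (is.na(agent$school_id)) home else agent$school_id)
  pl <- world$places
  hrow <- pl[match(home, pl$place_id)]
  if (pol == "out_of_home") {
    cand <- pl[kind != "household"]
    if (nrow(cand) == 0L) return(home)
    d <- coord_distance(hrow$x, hrow$y, cand$x, cand$y, world$frame)
    inr <- cand$place_id[d <= radius_km]
    if (length(inr) == 0L) inr <- cand$place_id[order(d, cand$place_id)][1]
    return(inr[sample.int(length(inr), 1L)])
  }
  if (pol == "service_site") {
    svcs <- strsplit(activity$mapped_services, ";", fixed = TRUE)[[1]]
    best <- NULL
    for (s in svcs) {
      nr <- nearest_resources(world, hrow, s, 1L)
      if (nrow(nr) && (is.null(best) || nr$distance_km < best$distance_km ||
                       (nr$distance_km == best$distance_km &&
                        nr$resource_id < best$resource_id)))
        best <- nr
    }
    if (is.null(best)) return(home)
    return(world$resources[match(best$resource_id, world$resources$resource_id), place_id])
  }
  abort_config("unresolvable location policy '%s'", pol)
}

#' A/B decision: use a known resource or continue the previous activity
#'
#' The candidate set is the agent's known resources whose service type is
#' mapped from the activity; each is scored `beta * exp(-d/d0) * gamma`
#' with `d` the distance from `from_place` to the resource. The
#' highest-scoring candidate (ties broken by lower resource id) is used
#' (decision A) iff its score exceeds the agent's activation threshold.
#'
#' @param agent one-row agent table
#' @param activity one-row catalog entry with `decision_type == "AB"`
#' @param store the agent's knowledge store (betas already current)
#' @param world a `crx_world`
#' @param dp [decision_params()]
#' @param from_place place id the agent starts from (default: household)
#' @return list with `decision` ("A"/"B"), and for A the chosen
#'   `resource_id`, its `place_id` and `score`
#' @export
decide_ab <- function(agent, activity, store, world, dp = decision_params(),
                      from_place = NULL) {
  stopifnot(activity$decision_type == "AB")
  svcs <- strsplit(activity$mapped_services, ";", fixed = TRUE)[[1]]
  if (nrow(store) == 0L) return(list(decision = "B"))
  res <- world$resources[match(store$resource_id, world$resources$resource_id)]
  keep <- res$service_type %in% svcs
  if (!any(keep)) return(list(decision = "B"))
  cand_res <- res[keep]
  cand_beta <- store$beta[keep]
  from <- from_place %||% agent$household_id
  fp <- world$places[match(from, world$places$place_id)]
  rp <- world$places[match(cand_res$place_id, world$places$place_id)]
  d <- coord_distance(fp$x, fp$y, rp$x, rp$y, world$frame)
  score <- cand_beta * exp(-d / dp$d0_km) * cand_res$inertia
  o <- order(-score, cand_res$resource_id)[1]
  if (score[o] > agent$activation) {
    list(decision = "A", resource_id = cand_res$resource_id[o],
         place_id = cand_res$place_id[o], score = score[o])
  } else {
    list(decision = "B", score = score[o])
  }
}

#' Peer information exchange within one co-located group
#'
#' For each receiver in increasing agent-id order whose current activity
#' has positive receipt propensity `p`, the number of firing contacts is
#' drawn as `Binomial(min(m, s - 1), p)` (equivalent to sampling up to `m`
#' potential givers without replacement and testing each against `p`); the
#' firing givers are then a uniform sample of the co-located others. Each
#' fired pair transmits the giver's top-beta resources (`k` of them under
#' the configured share policy); a giver with an empty store fires an
#' exchange event but transmits nothing. Receiver characteristics never
#' modulate the probability.
#'
#' @param group data.table with `agent_id` and `p` (receipt propensity of
#'   each member's current activity), all co-located at `place_id`
#' @param kn knowledge table (`agent_id`, `resource_id`, `beta`,
#'   `last_update`, `rx_derived`)
#' @param config [simulation_config()] (uses `contacts_per_agent_hour`,
#'   `shares_per_exchange`, `share_policy`, `knowledge`)
#' @param place_id place of co-location (recorded in events)
#' @param t hour index
#' @return list of `events` (exchange events) and `doses`
#'   (receiver/resource/rx_derived rows to be applied as Peer doses)
#' @export
exchange <- function(group, kn, config = simulation_config(),
                     place_id = NA_integer_, t = 0L) {
  group <- as.data.table(group)[order(agent_id)]
  s <- nrow(group)
  ev <- list(); dose <- list()
  if (s >= 2L) {
    lam <- config$knowledge$lambda
    for (i in seq_len(s)) {
      p <- group$p[i]
      if (p <= 0) next
      r <- group$agent_id[i]
      npot <- min(config$contacts_per_agent_hour, s - 1L)
      nf <- rbinom(1L, npot, p)
      if (nf == 0L) next
      others <- group$agent_id[group$agent_id != r]
      givers <- others[sample.int(length(others), nf)]
      for (g in givers) {
        st <- kn[agent_id == g]
        if (nrow(st) == 0L) {
          ev[[length(ev) + 1L]] <- data.table(hour = as.integer(t),
                                              giver_id = g, receiver_id = r,
                                              place_id = place_id,
                                              resource_id = NA_integer_)
          next
        }
        cur <- st$beta * lam^(t - st$last_update)
        k <- min(config$shares_per_exchange, nrow(st))
        sel <- if (config$share_policy == "top_beta") {
          order(-cur, st$resource_id)[seq_len(k)]
        } else {
          sample.int(nrow(st), k, prob = cur)
        }
        for (j in sel) {
          ev[[length(ev) + 1L]] <- data.table(hour = as.integer(t),
                                              giver_id = g, receiver_id = r,
                                              place_id = place_id,
                                              resource_id = st$resource_id[j])
          dose[[length(dose) + 1L]] <- data.table(receiver_id = r,
                                                  resource_id = st$resource_id[j],
                                                  rx_derived = st$rx_derived[j],
                                                  giver_id = g)
        }
      }
    }
  }
  list(events = data.table::rbindlist(ev), doses = data.table::rbindlist(dose))
}

## ---------------------------------------------------------------------------
## The engine proper
## ---------------------------------------------------------------------------

#' Run the hourly simulation
#'
#' For each simulated day every agent draws a fresh schedule template from
#' their demographically matched pool (weekday/weekend); each hour the
#' engine (1) moves agents per their activity's location policy, (2)
#' issues and delivers a HealtheRx to agents performing a clinic-trigger
#' activity at a clinic (at most one per agent per day), (3) runs peer
#' exchange among co-located agents, (4) resolves A/B use decisions for
#' eligible activities, and (5) leaves decay to lazy evaluation. All
#' randomness comes from one stream seeded with `config$seed`. Burn-in
#' hours are flagged in the logs, not dropped. Weekly knowledge snapshots
#' (decayed to the snapshot hour) are recorded at the end of each
#' simulated week.
#'
#' @section Reproducibility contract (RNG draw order):
#' 1. knowledge seeding (unless `initial_knowledge` is supplied): agents in
#'    increasing id order; per agent the low-stratum count, ids and betas,
#'    then mid, then far;
#' 2. per day: one uniform template draw per agent in increasing id order;
#' 3. per hour: one uniform draw per out-of-home agent in increasing id
#'    order; then one `rbinom` per eligible exchange receiver in (place,
#'    agent) order; then one giver sample per fired receiver in the same
#'    order (plus one weighted draw per transmission under the
#'    `beta_weighted` policy).
#' Clinic dosing, A/B decisions and decay draw nothing.
#'
#' @param world a `crx_world`
#' @param pool a `crx_pool`
#' @param config a [simulation_config()]
#' @param catalog condition catalog for HealtheRx generation
#' @return a `crx_run` list: `events` (dosing / exchange / use / visit
#'   data.tables, each with a `burn_in` flag), `healtherx` (item-level
#'   log), `snapshots` (per-week knowledge tables), `final_knowledge`,
#'   `trajectories`, `movement` (if logged), `meta`
#' @export
run_simulation <- function(world, pool, config = simulation_config(),
                           catalog = condition_catalog_default()) {
  stopifnot(inherits(world, "crx_world"), inherits(pool, "crx_pool"),
            inherits(config, "crx_simulation_config"))
  validate_world(world)
  agents <- world$agents
  n <- nrow(agents)
  n_places <- nrow(world$places)
  if (n_places == 0L) abort_config("world has no places")
  if (!identical(sort(world$places$place_id), seq_len(n_places)))
    abort_config("place ids must be contiguous 1..N for simulation")
  if (n > 0L && !identical(sort(agents$agent_id), seq_len(n)))
    abort_config("agent ids must be contiguous 1..N for simulation")

  set.seed(config$seed)
  kp <- config$knowledge
  lam <- kp$lambda
  cap <- kp$capacity
  eps <- kp$sources
  m_cap <- config$contacts_per_agent_hour
  n_hours <- config$n_days * 24L
  burn_hours <- config$burn_in_days * 24L

  ## -- catalog lookups ------------------------------------------------------
  cat_dt <- pool$catalog
  n_act <- nrow(cat_dt)
  p_rates <- config$p_rates %||% pool$p_rates
  act_p <- pmin(1, pmax(0, unname(p_rates[cat_dt$p_level]) *
                          ifelse(cat_dt$p_level == "none", 1,
                                 config$p_rate_multiplier)))
  POL <- c(home = 1L, work = 2L, school = 3L, out_of_home = 4L,
           service_site = 5L)
  act_pol <- unname(POL[cat_dt$location_policy])
  act_ab <- cat_dt$decision_type == "AB"
  act_trigger <- isTRUE_vec(cat_dt$clinic_trigger)
  svc_levels <- sort(unique(c(world$resources$service_type,
                              unlist(strsplit(cat_dt$mapped_services, ";")))))
  n_svc <- length(svc_levels)
  svc_allowed <- matrix(FALSE, n_act, max(1L, n_svc))
  for (a in seq_len(n_act)) {
    s <- strsplit(cat_dt$mapped_services[a], ";", fixed = TRUE)[[1]]
    svc_allowed[a, match(s[nzchar(s)], svc_levels)] <- TRUE
  }

  ## -- world lookups --------------------------------------------------------
  px <- world$places$x[order(world$places$place_id)]
  py <- world$places$y[order(world$places$place_id)]
  pkind <- world$places$kind[order(world$places$place_id)]
  is_clinic <- pkind == "clinic"
  res <- world$resources
  res_place <- res$place_id
  res_gamma <- res$inertia
  res_svc <- match(res$service_type, svc_levels)
  home <- agents$household_id
  workp <- agents$workplace_id
  school <- agents$school_id
  alpha <- agents$activation
  frame <- world$frame

  ## out-of-home candidate lists per household (indexed by place id)
  nonhh <- which(pkind != "household")
  oo_cand <- vector("list", n_places)
  for (hh in unique(home)) {
    d <- coord_distance(px[hh], py[hh], px[nonhh], py[nonhh], frame)
    ids <- nonhh[d <= config$out_of_home_radius_km]
    if (length(ids) == 0L && length(nonhh))
      ids <- nonhh[order(d, nonhh)][1]
    oo_cand[[hh]] <- ids
  }

  ## nearest mapped resource for service_site activities without a decision
  svc_none_acts <- which(act_pol == POL[["service_site"]] & !act_ab)
  svc_place <- list()
  for (a in svc_none_acts) {
    allowed <- which(svc_allowed[a, ])
    rs <- which(res_svc %in% allowed)
    tgt <- rep(NA_integer_, n)
    if (length(rs)) {
      for (hh in unique(home)) {
        d <- coord_distance(px[hh], py[hh], px[res_place[rs]],
                            py[res_place[rs]], frame)
        best <- rs[order(d, res$resource_id[rs])][1]
        tgt[home == hh] <- res_place[best]
      }
    }
    svc_place[[as.character(a)]] <- tgt
  }

  ## matched template sets per agent
  band <- as.character(age_band(agents$age))
  matched <- list(weekday = vector("list", n), weekend = vector("list", n))
  for (dt_ in c("weekday", "weekend")) {
    keys <- stratum_key(band, agents$sex, agents$race, agents$ethnicity, dt_)
    ukeys <- unique(keys)
    lk <- lapply(ukeys, function(k) {
      ids <- pool$index[[k]]
      if (is.null(ids)) {
        parts <- strsplit(k, "|", fixed = TRUE)[[1]]
        ids <- match_templates(pool, parts[1], parts[2], parts[3], parts[4], parts[5])
      }
      ids
    })
    names(lk) <- ukeys
    matched[[dt_]] <- lk[keys]
  }

  ## -- knowledge state (flat vectors + per-agent row index) -----------------
  if (!is.null(config$initial_knowledge)) {
    kn0 <- as.data.table(config$initial_knowledge)
  } else {
    kn0 <- seed_world_knowledge(world, config$seeding, kp)
  }
  cap0 <- max(1024L, 2L * nrow(kn0))
  kn_agent <- rep(-1L, cap0); kn_res <- integer(cap0)
  kn_beta <- numeric(cap0); kn_last <- integer(cap0); kn_rx <- logical(cap0)
  n_kn <- nrow(kn0)
  if (n_kn) {
    kn_agent[1:n_kn] <- kn0$agent_id; kn_res[1:n_kn] <- kn0$resource_id
    kn_beta[1:n_kn] <- kn0$beta; kn_last[1:n_kn] <- kn0$last_update
    kn_rx[1:n_kn] <- kn0$rx_derived
  }
  M <- max(res$resource_id, 1L) + 1L
  rows_of <- if (n) split(seq_len(n_kn), factor(kn_agent[seq_len(n_kn)],
                                                levels = seq_len(n)))
             else list()
  cnt <- lengths(rows_of)
  grow <- function(need) {
    while (n_kn + need > length(kn_agent)) {
      extra <- length(kn_agent)
      kn_agent <<- c(kn_agent, rep(-1L, extra))
      kn_res <<- c(kn_res, integer(extra))
      kn_beta <<- c(kn_beta, numeric(extra))
      kn_last <<- c(kn_last, integer(extra))
      kn_rx <<- c(kn_rx, logical(extra))
    }
  }

  ## top-of-store cache: the decayed-beta argmax is order-stable under lazy
  ## geometric decay because beta_j * lambda^(t - s_j) ranks like
  ## beta_j * lambda^(-s_j) for every t
  top_res <- integer(n); top_key <- rep(-Inf, n); top_rx <- logical(n)
  if (n_kn) {
    key0 <- kn_beta[1:n_kn] * lam^(-kn_last[1:n_kn])
    o <- order(kn_agent[1:n_kn], -key0, kn_res[1:n_kn])
    first <- o[!duplicated(kn_agent[1:n_kn][o])]
    top_res[kn_agent[first]] <- kn_res[first]
    top_key[kn_agent[first]] <- key0[first]
    top_rx[kn_agent[first]] <- kn_rx[first]
  }
  rescan_top <- function(a) {
    rws <- rows_of[[a]]
    if (length(rws) == 0L) {
      top_res[a] <<- 0L; top_key[a] <<- -Inf; top_rx[a] <<- FALSE
      return(invisible())
    }
    key <- kn_beta[rws] * lam^(-kn_last[rws])
    j <- rws[order(-key, kn_res[rws])][1]
    top_res[a] <<- kn_res[j]
    top_key[a] <<- kn_beta[j] * lam^(-kn_last[j])
    top_rx[a] <<- kn_rx[j]
  }
  bump_top <- function(a, r, b, rx, lamneg) {
    key <- b * lamneg
    if (key > top_key[a] || (key == top_key[a] && r < top_res[a])) {
      top_res[a] <<- r; top_key[a] <<- key; top_rx[a] <<- rx
    } else if (r == top_res[a]) {
      top_key[a] <<- key; top_rx[a] <<- rx
    }
  }

  ## -- event accumulators ---------------------------------------------------
  ev_dose <- list(); ev_exch <- list(); ev_use <- list(); ev_visit <- list()
  rx_rows <- list(); move_rows <- list(); snaps <- list()
  rx_counter <- 0L
  fallback_work <- 0L; fallback_school <- 0L

  ## track trajectories
  track <- config$track
  if (!is.null(track)) {
    track <- as.data.table(track)
    traj <- matrix(NA_real_, n_hours, nrow(track))
  }

  ## sequential dose application for one at-capacity-risk agent (exact
  ## upsert semantics, in dose order)
  apply_seq <- function(a, rs, rxs, e, t, lamneg) {
    out_beta <- numeric(length(rs))
    for (q in seq_along(rs)) {
      r <- rs[q]
      rws <- rows_of[[a]]
      j <- rws[match(r, kn_res[rws])]
      if (!is.na(j)) {
        b <- kn_beta[j] * lam^(t - kn_last[j])
        b <- lam * b^e * (1 - b) + b
        kn_beta[j] <<- b; kn_last[j] <<- t
        kn_rx[j] <<- kn_rx[j] | rxs[q]
        bump_top(a, r, b, kn_rx[j], lamneg)
        out_beta[q] <- b
      } else {
        b <- kp$beta_init
        b <- lam * b^e * (1 - b) + b
        out_beta[q] <- b
        if (cnt[a] < cap) {
          grow(1L); n_kn <<- n_kn + 1L
          kn_agent[n_kn] <<- a; kn_res[n_kn] <<- r; kn_beta[n_kn] <<- b
          kn_last[n_kn] <<- t; kn_rx[n_kn] <<- rxs[q]
          rows_of[[a]] <<- c(rws, n_kn); cnt[a] <<- cnt[a] + 1L
          bump_top(a, r, b, rxs[q], lamneg)
        } else {
          dec <- kn_beta[rws] * lam^(t - kn_last[rws])
          jm <- rws[order(dec, kn_res[rws])][1]
          if (b > dec[match(jm, rws)]) {
            was_top <- kn_res[jm] == top_res[a]
            kn_agent[jm] <<- -1L
            rows_of[[a]] <<- setdiff(rws, jm)
            grow(1L); n_kn <<- n_kn + 1L
            kn_agent[n_kn] <<- a; kn_res[n_kn] <<- r; kn_beta[n_kn] <<- b
            kn_last[n_kn] <<- t; kn_rx[n_kn] <<- rxs[q]
            rows_of[[a]] <<- c(rows_of[[a]], n_kn)
            if (was_top) rescan_top(a) else bump_top(a, r, b, rxs[q], lamneg)
          }
        }
      }
    }
    out_beta
  }

  ## row index of (agent, resource) entries via the per-agent index; NA if
  ## absent (O(store size) per lookup, never a global scan)
  find_rows <- function(a, r) {
    out <- integer(length(a))
    for (q in seq_along(a)) {
      rws <- rows_of[[a[q]]]
      j <- match(r[q], kn_res[rws])
      out[q] <- if (is.na(j)) NA_integer_ else rws[j]
    }
    out
  }

  ## batched dose application; `a`, `r`, `rx` in dose order, one source
  apply_doses <- function(a, r, rx, source, t, giver = NULL, place = NULL) {
    if (length(a) == 0L) return(invisible())
    e <- eps[[source]]
    lamneg <- lam^(-t)
    beta_after <- numeric(length(a))
    qkey <- as.numeric(a) * M + r
    rowidx <- find_rows(a, r)
    ## agents where capacity interactions are possible go through the exact
    ## sequential path in original order
    new_per <- tabulate(a[is.na(rowidx)], nbins = n)
    risk <- cnt + new_per > cap
    seq_sel <- risk[a]
    if (any(seq_sel)) {
      for (aa in unique(a[seq_sel])) {
        ii <- which(seq_sel & a == aa)
        beta_after[ii] <- apply_seq(aa, r[ii], rx[ii], e, t, lamneg)
      }
    }
    bi <- which(!seq_sel)
    if (length(bi)) {
      ab <- a[bi]; rb <- r[bi]; rxb <- rx[bi]; qb <- qkey[bi]
      firstpos <- !duplicated(qb)
      uq <- qb[firstpos]
      occ <- match(qb, uq)              # occurrence group of each dose
      nrep <- tabulate(occ)
      ua <- ab[firstpos]; ur <- rb[firstpos]
      urx <- as.logical(tapply(rxb, occ, any))
      midx <- rowidx[bi][firstpos]
      hit <- !is.na(midx)
      b0 <- numeric(length(uq))
      if (any(hit)) {
        rows <- midx[hit]
        b0[hit] <- kn_beta[rows] * lam^(t - kn_last[rows])
      }
      b0[!hit] <- kp$beta_init
      ## compound boosts; record the value after each occurrence
      b <- b0
      pos_in_occ <- stats::ave(seq_along(occ), occ, FUN = seq_along)
      pass <- 1L
      repeat {
        todo <- nrep >= pass
        if (!any(todo)) break
        b[todo] <- lam * b[todo]^e * (1 - b[todo]) + b[todo]
        sel <- pos_in_occ == pass
        beta_after[bi[sel]] <- b[occ[sel]]
        pass <- pass + 1L
      }
      ## write back
      if (any(hit)) {
        rows <- midx[hit]
        kn_beta[rows] <<- b[hit]
        kn_last[rows] <<- t
        kn_rx[rows] <<- kn_rx[rows] | urx[hit]
        for (z in which(hit))
          bump_top(ua[z], ur[z], b[z], kn_rx[midx[z]], lamneg)
      }
      miss <- which(!hit)
      if (length(miss)) {
        grow(length(miss))
        idx <- n_kn + seq_along(miss)
        n_kn <<- n_kn + length(miss)
        kn_agent[idx] <<- ua[miss]; kn_res[idx] <<- ur[miss]
        kn_beta[idx] <<- b[miss]; kn_last[idx] <<- t; kn_rx[idx] <<- urx[miss]
        for (z in seq_along(miss)) {
          aa <- ua[miss[z]]
          rows_of[[aa]] <<- c(rows_of[[aa]], idx[z])
          cnt[aa] <<- cnt[aa] + 1L
          bump_top(aa, ur[miss[z]], b[miss[z]], urx[miss[z]], lamneg)
        }
      }
    }
    ev_dose[[length(ev_dose) + 1L]] <<- list(
      hour = rep(as.integer(t), length(a)), agent_id = a, resource_id = r,
      source = rep(source, length(a)),
      giver_id = if (is.null(giver)) rep(NA_integer_, length(a)) else giver,
      place_id = if (is.null(place)) rep(NA_integer_, length(a)) else place,
      beta_after = beta_after)
    invisible()
  }

  ## HealtheRx cache (deterministic per agent), with a vectorized builder
  ## equivalent to generate_healtherx(): round-robin across alphabetically
  ## sorted indicated services, nearest-first (ties by resource id),
  ## de-duplicated, truncated at 40
  rx_cache <- vector("list", n)
  res_by_svc <- split(res$resource_id, res$service_type)
  cond_svc <- local({
    cc <- catalog[, .(services = paste(unique(unlist(
      strsplit(services, ";", fixed = TRUE))), collapse = ";")),
      by = condition_code]
    setNames(strsplit(cc$services, ";", fixed = TRUE), cc$condition_code)
  })
  build_rx_items <- function(i, max_items = 40L) {
    base <- status_services(band[i])[[1]]
    conds <- agents$conditions[i]
    extra <- character()
    if (!is.na(conds) && nzchar(conds)) {
      codes <- strsplit(conds, ";", fixed = TRUE)[[1]]
      extra <- unlist(cond_svc[codes], use.names = FALSE)
    }
    svcs <- sort(unique(c(base, extra)))
    hh <- home[i]
    per_svc <- lapply(svcs, function(s) {
      ids <- res_by_svc[[s]]
      if (is.null(ids)) return(integer(0))
      d <- coord_distance(px[hh], py[hh], px[res_place[ids]],
                          py[res_place[ids]], frame)
      head(ids[order(d, ids)], max_items)
    })
    items <- integer(0)
    depth <- if (length(per_svc)) max(lengths(per_svc)) else 0L
    for (rank in seq_len(depth)) {
      for (v in per_svc) if (rank <= length(v)) items <- c(items, v[rank])
      if (length(unique(items)) >= max_items) break
    }
    items <- unique(items)
    if (length(items) > max_items) items <- items[seq_len(max_items)]
    items
  }

  prev_act <- integer(n)
  prev_place <- home
  HOME <- POL[["home"]]; WORK <- POL[["work"]]; SCHOOL <- POL[["school"]]
  OUT <- POL[["out_of_home"]]; SVC <- POL[["service_site"]]
  last_rx_day <- rep(-1L, n)

  for (d in seq_len(config$n_days) - 1L) {
    day_type <- if (d %% 7L < 5L) "weekday" else "weekend"
    mm <- matched[[day_type]]
    tmpl <- integer(n)
    for (i in seq_len(n)) {
      ids <- mm[[i]]
      tmpl[i] <- ids[sample.int(length(ids), 1L)]
    }
    S <- pool$hours[tmpl, , drop = FALSE]
    for (h in 0:23) {
      t <- d * 24L + h
      act <- S[, h + 1L]
      pol <- act_pol[act]
      place <- integer(n)
      sel <- pol == HOME; place[sel] <- home[sel]
      sel <- pol == WORK
      if (any(sel)) {
        w <- workp[sel]
        miss <- is.na(w)
        fallback_work <- fallback_work + sum(miss)
        w[miss] <- home[sel][miss]
        place[sel] <- w
      }
      sel <- pol == SCHOOL
      if (any(sel)) {
        w <- school[sel]
        miss <- is.na(w)
        fallback_school <- fallback_school + sum(miss)
        w[miss] <- home[sel][miss]
        place[sel] <- w
      }
      sel <- pol == SVC & !act_ab[act]
      if (any(sel)) {
        for (a_ in unique(act[sel])) {
          s2 <- sel & act == a_
          tgt <- svc_place[[as.character(a_)]][s2]
          tgt[is.na(tgt)] <- home[s2][is.na(tgt)]
          place[s2] <- tgt
        }
      }
      sel <- pol == SVC & act_ab[act]
      place[sel] <- prev_place[sel]
      oo <- which(pol == OUT)
      for (i in oo) {
        cand <- oo_cand[[home[i]]]
        place[i] <- if (length(cand) == 0L) home[i]
                    else cand[sample.int(length(cand), 1L)]
      }

      ## (2) clinic dosing
      trig <- which(act_trigger[act] & is_clinic[place] & last_rx_day < d)
      if (length(trig)) {
        da <- integer(0); dr <- integer(0)
        for (i in trig) {
          items <- rx_cache[[i]]
          if (is.null(items)) {
            items <- build_rx_items(i)
            rx_cache[[i]] <- items
          }
          rx_counter <- rx_counter + 1L
          last_rx_day[i] <- d
          ev_visit[[length(ev_visit) + 1L]] <- list(
            hour = as.integer(t), agent_id = i, clinic_id = place[i],
            rx_id = rx_counter)
          ni <- length(items)
          if (ni) {
            rx_rows[[length(rx_rows) + 1L]] <- list(
              rx_id = rep(rx_counter, ni), agent_id = rep(i, ni),
              clinic_id = rep(place[i], ni), hour = rep(as.integer(t), ni),
              delivery_mode = rep(config$delivery$delivery_mode, ni),
              rank = seq_len(ni), resource_id = items)
            da <- c(da, rep(i, ni)); dr <- c(dr, items)
          }
        }
        if (length(da))
          apply_doses(da, dr, rep(TRUE, length(da)),
                      config$delivery$dose_source, t,
                      place = place[da])
      }

      ## (3) peer exchange (simultaneous within the hour: transmissions
      ## read the state at step start, doses applied at step end)
      pvec <- act_p[act]
      sizes <- tabulate(place, nbins = n_places)
      gsz <- sizes[place]
      ercv <- which(pvec > 0 & gsz >= 2L)
      if (length(ercv)) {
        ercv <- ercv[order(place[ercv], ercv)]
        npot <- pmin(m_cap, gsz[ercv] - 1L)
        nf <- rbinom(length(ercv), npot, pvec[ercv])
        fired <- which(nf > 0L)
        if (length(fired)) {
          tr_res <- top_res; tr_rx <- top_rx  # state at step start
          fp <- place[ercv[fired]]
          need <- which(place %in% unique(fp))
          memb <- split(need, place[need])
          mkey <- as.integer(names(memb))
          mpos <- match(fp, mkey)
          gl <- vector("list", length(fired))
          for (z in seq_along(fired)) {
            rcv <- ercv[fired[z]]
            v <- memb[[mpos[z]]]
            others <- v[v != rcv]
            gl[[z]] <- others[sample.int(length(others), nf[fired[z]])]
          }
          giv <- unlist(gl)
          rcv <- rep(ercv[fired], nf[fired])
          plc <- rep(fp, nf[fired])
          tres <- tr_res[giv]
          ev_exch[[length(ev_exch) + 1L]] <- list(
            hour = rep(as.integer(t), length(giv)), giver_id = giv,
            receiver_id = rcv, place_id = plc,
            resource_id = ifelse(tres > 0L, tres, NA_integer_))
          has <- tres > 0L
          if (any(has))
            apply_doses(rcv[has], tres[has], tr_rx[giv[has]], "Peer", t,
                        giver = giv[has], place = plc[has])
        }
      }

      coloc <- place  # where each agent was during co-location/exchange

      ## (4) A/B decisions
      dec <- which(act_ab[act])
      if (length(dec)) {
        lens <- cnt[dec]
        keep_d <- dec[lens > 0L]
        if (length(keep_d)) {
          rws <- unlist(rows_of[keep_d], use.names = FALSE)
          ag <- rep(keep_d, cnt[keep_d])
          rr <- kn_res[rws]
          ok <- svc_allowed[cbind(act[ag], res_svc[rr])]
          if (any(ok)) {
            ag2 <- ag[ok]; rr2 <- rr[ok]; rw2 <- rws[ok]
            bcur <- kn_beta[rw2] * lam^(t - kn_last[rw2])
            dd <- coord_distance(px[prev_place[ag2]], py[prev_place[ag2]],
                                 px[res_place[rr2]], py[res_place[rr2]], frame)
            score <- bcur * exp(-dd / config$decision$d0_km) * res_gamma[rr2]
            o <- order(ag2, -score, rr2)
            first <- o[!duplicated(ag2[o])]
            wa <- ag2[first]; wr <- rr2[first]; ws <- score[first]
            useA <- ws > alpha[wa]
            if (any(useA)) {
              ua_ <- wa[useA]; ur_ <- wr[useA]
              place[ua_] <- res_place[ur_]
              ev_use[[length(ev_use) + 1L]] <- list(
                hour = rep(as.integer(t), length(ua_)), agent_id = ua_,
                resource_id = ur_, place_id = res_place[ur_])
              apply_doses(ua_, ur_, rep(FALSE, length(ua_)), "Use", t,
                          place = res_place[ur_])
            }
            bset <- setdiff(dec, wa[useA])
          } else bset <- dec
        } else bset <- dec
        ## decision B (or no candidates): continue the previous activity
        bset <- bset[prev_act[bset] > 0L]
        act[bset] <- prev_act[bset]
        place[bset] <- prev_place[bset]
      }

      ## (5) bookkeeping
      if (config$log_movement)
        move_rows[[length(move_rows) + 1L]] <- list(
          hour = rep(as.integer(t), n), agent_id = seq_len(n),
          place_id = coloc, final_place_id = place)
      if (!is.null(track)) {
        mi <- find_rows(track$agent_id, track$resource_id)
        traj[t + 1L, ] <- ifelse(is.na(mi), NA_real_,
                                 kn_beta[mi] * lam^(t - kn_last[mi]))
      }
      if ((t + 1L) %% 168L == 0L) {
        wk <- (t + 1L) %/% 168L
        alive <- which(kn_agent[seq_len(n_kn)] > 0L)
        snaps[[as.character(wk)]] <- data.table(
          agent_id = kn_agent[alive], resource_id = kn_res[alive],
          beta = kn_beta[alive] * lam^(t - kn_last[alive]),
          rx_derived = kn_rx[alive], last_update = kn_last[alive])
      }
      prev_act <- act
      prev_place <- place
    }
  }

  ## final tables
  mk <- function(lst, proto) {
    if (!length(lst)) return(as.data.table(proto))
    data.table::rbindlist(lapply(lst, as.data.table))
  }
  dosing <- mk(ev_dose, list(hour = integer(), agent_id = integer(),
                             resource_id = integer(), source = character(),
                             giver_id = integer(), place_id = integer(),
                             beta_after = numeric()))
  exch <- mk(ev_exch, list(hour = integer(), giver_id = integer(),
                           receiver_id = integer(), place_id = integer(),
                           resource_id = integer()))
  use <- mk(ev_use, list(hour = integer(), agent_id = integer(),
                         resource_id = integer(), place_id = integer()))
  visit <- mk(ev_visit, list(hour = integer(), agent_id = integer(),
                             clinic_id = integer(), rx_id = integer()))
  rxlog <- mk(rx_rows, list(rx_id = integer(), agent_id = integer(),
                            clinic_id = integer(), hour = integer(),
                            delivery_mode = character(), rank = integer(),
                            resource_id = integer()))
  for (tb in list(dosing, exch, use, visit))
    tb[, burn_in := hour < burn_hours]
  alive <- which(kn_agent[seq_len(n_kn)] > 0L)
  t_end <- n_hours - 1L
  final_kn <- data.table(agent_id = kn_agent[alive], resource_id = kn_res[alive],
                         beta = kn_beta[alive] * lam^(t_end - kn_last[alive]),
                         rx_derived = kn_rx[alive], last_update = kn_last[alive])
  setkey(final_kn, agent_id, resource_id)
  structure(list(
    events = list(dosing = dosing, exchange = exch, use = use, visit = visit),
    healtherx = rxlog,
    snapshots = snaps,
    final_knowledge = final_kn,
    trajectories = if (!is.null(track)) list(pairs = track, beta = traj) else NULL,
    movement = mk(move_rows, list(hour = integer(), agent_id = integer(),
                                  place_id = integer(),
                                  final_place_id = integer())),
    meta = list(seed = config$seed, n_days = config$n_days,
                burn_in_days = config$burn_in_days, n_agents = n,
                n_exchange = nrow(exch), n_rx = rx_counter,
                fallback_work_hours = fallback_work,
                fallback_school_hours = fallback_school,
                delivery_mode = config$delivery$delivery_mode),
    config = config
  ), class = "crx_run")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.crx_run <- function(x, ...) {
  cat(sprintf(
    "<crx_run> %d agents x %d days: %d HealtheRxs, %d dosing, %d exchange, %d use events\n",
    x$meta$n_agents, x$meta$n_days, x$meta$n_rx,
    nrow(x$events$dosing), nrow(x$events$exchange), nrow(x$events$use)))
  invisible(x)
}
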