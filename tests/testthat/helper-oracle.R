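# A straight-line brute-force reference simulator, written independently of
# the engine's vectorized internals. It follows the engine's documented
# step order and RNG draw protocol (see ?run_simulation) with plain nested
# loops and per-agent list stores, so that for identical inputs the two
# implementations must produce identical event logs.

oracle_run <- function(world, pool, config) {
  set.seed(config$seed)
  ag <- as.data.frame(world$agents)
  pl <- as.data.frame(world$places)
  pl <- pl[order(pl$place_id), ]
  res <- as.data.frame(world$resources)
  cata <- as.data.frame(pool$catalog)
  kp <- config$knowledge
  lam <- kp$lambda
  eps <- kp$sources
  n <- nrow(ag)
  n_places <- nrow(pl)
  m_cap <- config$contacts_per_agent_hour
  prate <- if (!is.null(config$p_rates)) config$p_rates else pool$p_rates
  actp <- vapply(seq_len(nrow(cata)), function(a) {
    r <- prate[[cata$p_level[a]]]
    if (cata$p_level[a] != "none")
      r <- min(1, max(0, r * config$p_rate_multiplier))
    r
  }, 1)
  dist2 <- function(p1, p2)
    sqrt((pl$x[p1] - pl$x[p2])^2 + (pl$y[p1] - pl$y[p2])^2)

  ## stores as plain per-agent lists
  stores <- lapply(seq_len(n), function(i)
    list(res = integer(0), beta = numeric(0), last = integer(0),
         rx = logical(0)))
  stopifnot(!is.null(config$initial_knowledge))  # reference needs fixed seeds
  kn0 <- as.data.frame(config$initial_knowledge)
  for (q in seq_len(nrow(kn0))) {
    i <- kn0$agent_id[q]
    stores[[i]]$res <- c(stores[[i]]$res, kn0$resource_id[q])
    stores[[i]]$beta <- c(stores[[i]]$beta, kn0$beta[q])
    stores[[i]]$last <- c(stores[[i]]$last, kn0$last_update[q])
    stores[[i]]$rx <- c(stores[[i]]$rx, kn0$rx_derived[q])
  }

  ## sequential dose (upsert) with lazy geometric decay; returns beta_after
  dose1 <- function(i, r, src, rxf, t) {
    st <- stores[[i]]
    j <- match(r, st$res)
    e <- eps[[src]]
    if (!is.na(j)) {
      b <- st$beta[j] * lam^(t - st$last[j])
      b <- lam * b^e * (1 - b) + b
      st$beta[j] <- b; st$last[j] <- t; st$rx[j] <- st$rx[j] | rxf
    } else {
      b <- kp$beta_init
      b <- lam * b^e * (1 - b) + b
      if (length(st$res) < kp$capacity) {
        st$res <- c(st$res, r); st$beta <- c(st$beta, b)
        st$last <- c(st$last, t); st$rx <- c(st$rx, rxf)
      } else {
        cb <- st$beta * lam^(t - st$last)
        o <- order(cb, st$res)[1]
        if (b > cb[o]) {
          st$res[o] <- r; st$beta[o] <- b; st$last[o] <- t; st$rx[o] <- rxf
        }
      }
    }
    stores[[i]] <<- st
    b
  }
  top_of <- function(i, t) {
    st <- stores[[i]]
    if (length(st$res) == 0L) return(NULL)
    cb <- st$beta * lam^(t - st$last)
    j <- order(-cb, st$res)[1]
    list(res = st$res[j], rx = st$rx[j], beta = cb[j])
  }

  ## deterministic prescription builder (round-robin, nearest-first)
  base_services <- function(age) {
    s <- c("fitness", "fresh_produce", "spiritual_services")
    if (age >= 66) s <- c(s, "senior_services", "walking_group")
    s
  }
  rx_items <- function(i, max_items = 40L) {
    svcs <- sort(unique(base_services(ag$age[i])))  # mini agents: no conditions
    hh <- ag$household_id[i]
    per <- lapply(svcs, function(s) {
      ids <- res$resource_id[res$service_type == s]
      if (!length(ids)) return(integer(0))
      d <- dist2(hh, res$place_id[match(ids, res$resource_id)])
      ids[order(d, ids)][seq_len(min(length(ids), max_items))]
    })
    items <- integer(0)
    for (rank in seq_len(max(c(0L, lengths(per))))) {
      for (v in per) if (rank <= length(v)) items <- c(items, v[rank])
      if (length(unique(items)) >= max_items) break
    }
    items <- unique(items)
    items[seq_len(min(length(items), max_items))]
  }

  ## out-of-home candidates (ascending place id), as documented
  nonhh <- pl$place_id[pl$kind != "household"]
  oo_of <- function(hh) {
    d <- dist2(hh, nonhh)
    ids <- nonhh[d <= config$out_of_home_radius_km]
    if (!length(ids) && length(nonhh)) ids <- nonhh[order(d, nonhh)][1]
    ids
  }
  ## nearest mapped resource place for no-decision service_site activities
  svc_target <- function(i, a) {
    svcs <- strsplit(cata$mapped_services[a], ";", fixed = TRUE)[[1]]
    ids <- res$resource_id[res$service_type %in% svcs]
    if (!length(ids)) return(ag$household_id[i])
    d <- dist2(ag$household_id[i], res$place_id[match(ids, res$resource_id)])
    best <- ids[order(d, ids)][1]
    res$place_id[match(best, res$resource_id)]
  }

  ev_dose <- list(); ev_exch <- list(); ev_use <- list(); ev_visit <- list()
  rx_rows <- list(); move_rows <- list()
  rx_counter <- 0L
  prev_act <- integer(n)
  prev_place <- ag$household_id
  last_rx_day <- rep(-1L, n)
  src_clin <- config$delivery$dose_source

  for (d in seq_len(config$n_days) - 1L) {
    day_type <- if (d %% 7L < 5L) "weekday" else "weekend"
    tmpl <- integer(n)
    for (i in seq_len(n)) {
      key <- paste(as.character(crxsim::age_band(ag$age[i])), ag$sex[i],
                   ag$race[i], ag$ethnicity[i], day_type, sep = "|")
      ids <- pool$index[[key]]
      tmpl[i] <- ids[sample.int(length(ids), 1L)]
    }
    for (h in 0:23) {
      t <- d * 24L + h
      act <- pool$hours[tmpl, h + 1L]
      ## (1) movement
      place <- integer(n)
      for (i in seq_len(n)) {
        a <- act[i]
        pol <- cata$location_policy[a]
        place[i] <- switch(pol,
          home = ag$household_id[i],
          work = if (is.na(ag$workplace_id[i])) ag$household_id[i]
                 else ag$workplace_id[i],
          school = if (is.na(ag$school_id[i])) ag$household_id[i]
                   else ag$school_id[i],
          out_of_home = {
            cand <- oo_of(ag$household_id[i])
            if (!length(cand)) ag$household_id[i]
            else cand[sample.int(length(cand), 1L)]
          },
          service_site = if (cata$decision_type[a] == "AB") prev_place[i]
                         else svc_target(i, a))
      }
      ## (2) clinic dosing
      for (i in seq_len(n)) {
        a <- act[i]
        if (!isTRUE(cata$clinic_trigger[a])) next
        if (pl$kind[place[i]] != "clinic" || last_rx_day[i] >= d) next
        items <- rx_items(i)
        rx_counter <- rx_counter + 1L
        last_rx_day[i] <- d
        ev_visit[[length(ev_visit) + 1L]] <-
          data.frame(hour = t, agent_id = i, clinic_id = place[i],
                     rx_id = rx_counter)
        for (q in seq_along(items)) {
          rx_rows[[length(rx_rows) + 1L]] <-
            data.frame(rx_id = rx_counter, agent_id = i,
                       clinic_id = place[i], hour = t,
                       delivery_mode = config$delivery$delivery_mode,
                       rank = q, resource_id = items[q])
          b <- dose1(i, items[q], src_clin, TRUE, t)
          ev_dose[[length(ev_dose) + 1L]] <-
            data.frame(hour = t, agent_id = i, resource_id = items[q],
                       source = src_clin, giver_id = NA_integer_,
                       place_id = place[i], beta_after = b)
        }
      }
      ## (3) exchange: transmissions read state at step start
      tops <- lapply(seq_len(n), top_of, t = t)
      sizes <- tabulate(place, nbins = n_places)
      ## pass 1: one rbinom per eligible receiver in (place, agent) order
      recv <- integer(0); nfire <- integer(0)
      for (p_ in sort(unique(place))) {
        if (sizes[p_] < 2L) next
        for (i in sort(which(place == p_))) {
          p <- actp[act[i]]
          if (p <= 0) next
          npot <- min(m_cap, sizes[p_] - 1L)
          recv <- c(recv, i)
          nfire <- c(nfire, rbinom(1L, npot, p))
        }
      }
      ## pass 2: giver samples for fired receivers, in the same order
      pairs <- list()
      for (z in seq_along(recv)) {
        if (nfire[z] == 0L) next
        i <- recv[z]
        v <- sort(which(place == place[i]))
        others <- v[v != i]
        givers <- others[sample.int(length(others), nfire[z])]
        for (g in givers)
          pairs[[length(pairs) + 1L]] <- c(g = g, r = i)
      }
      for (pr in pairs) {
        g <- pr[["g"]]; rcv <- pr[["r"]]
        tp <- tops[[g]]
        ev_exch[[length(ev_exch) + 1L]] <-
          data.frame(hour = t, giver_id = g, receiver_id = rcv,
                     place_id = place[rcv],
                     resource_id = if (is.null(tp)) NA_integer_ else tp$res)
      }
      for (pr in pairs) {
        g <- pr[["g"]]; rcv <- pr[["r"]]
        tp <- tops[[g]]
        if (is.null(tp)) next
        b <- dose1(rcv, tp$res, "Peer", tp$rx, t)
        ev_dose[[length(ev_dose) + 1L]] <-
          data.frame(hour = t, agent_id = rcv, resource_id = tp$res,
                     source = "Peer", giver_id = g, place_id = place[rcv],
                     beta_after = b)
      }
      coloc <- place
      ## (4) A/B decisions
      usersA <- integer(0)
      use_ev <- list(); use_dose <- list()
      for (i in seq_len(n)) {
        a <- act[i]
        if (cata$decision_type[a] != "AB") next
        st <- stores[[i]]
        svcs <- strsplit(cata$mapped_services[a], ";", fixed = TRUE)[[1]]
        keep <- which(res$service_type[match(st$res, res$resource_id)] %in% svcs)
        if (length(keep)) {
          cb <- st$beta[keep] * lam^(t - st$last[keep])
          rpl <- res$place_id[match(st$res[keep], res$resource_id)]
          dd <- dist2(prev_place[i], rpl)
          gam <- res$inertia[match(st$res[keep], res$resource_id)]
          score <- cb * exp(-dd / config$decision$d0_km) * gam
          o <- order(-score, st$res[keep])[1]
          if (score[o] > ag$activation[i]) {
            rwin <- st$res[keep][o]
            place[i] <- rpl[o]
            usersA <- c(usersA, i)
            use_ev[[length(use_ev) + 1L]] <-
              data.frame(hour = t, agent_id = i, resource_id = rwin,
                         place_id = rpl[o])
            use_dose[[length(use_dose) + 1L]] <- c(i = i, r = rwin)
            next
          }
        }
        if (prev_act[i] > 0L) {
          act[i] <- prev_act[i]
          place[i] <- prev_place[i]
        }
      }
      for (z in seq_along(use_ev)) {
        ev_use[[length(ev_use) + 1L]] <- use_ev[[z]]
        ud <- use_dose[[z]]
        b <- dose1(ud[["i"]], ud[["r"]], "Use", FALSE, t)
        ev_dose[[length(ev_dose) + 1L]] <-
          data.frame(hour = t, agent_id = ud[["i"]], resource_id = ud[["r"]],
                     source = "Use", giver_id = NA_integer_,
                     place_id = use_ev[[z]]$place_id, beta_after = b)
      }
      ## (5) bookkeeping
      if (config$log_movement)
        move_rows[[length(move_rows) + 1L]] <-
          data.frame(hour = t, agent_id = seq_len(n), place_id = coloc,
                     final_place_id = place)
      prev_act <- act
      prev_place <- place
    }
  }
  cmb <- function(lst) if (length(lst)) do.call(rbind, lst) else NULL
  list(dosing = cmb(ev_dose), exchange = cmb(ev_exch), use = cmb(ev_use),
       visit = cmb(ev_visit), healtherx = cmb(rx_rows),
       movement = cmb(move_rows), stores = stores)
}

## strip burn-in flags / keys and compare an engine table to a reference one
expect_log_equal <- function(engine_tb, oracle_df) {
  e <- as.data.frame(engine_tb)
  e$burn_in <- NULL
  if (is.null(oracle_df)) {
    expect_equal(nrow(e), 0L)
  } else {
    rownames(e) <- NULL
    rownames(oracle_df) <- NULL
    expect_equal(e, oracle_df, tolerance = 1e-12)
  }
}
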