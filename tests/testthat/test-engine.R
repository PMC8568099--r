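# Engine semantics: movement, exchange, decisions, and full-log equivalence
# with the straight-line reference simulator.

mini_sim_config <- function(...) {
  simulation_config(n_days = 2L, burn_in_days = 1L, seed = 11L,
                    initial_knowledge = mini_kn(), log_movement = TRUE, ...)
}

test_that("engine event logs match the brute-force reference implementation", {
  world <- mini_world()
  pool <- mini_pool()
  for (seed in c(11L, 202L, 3003L)) {
    cfg <- mini_sim_config()
    cfg$seed <- seed
    run <- run_simulation(world, pool, cfg)
    ref <- oracle_run(world, pool, cfg)
    expect_log_equal(run$events$visit, ref$visit)
    expect_log_equal(run$healtherx, ref$healtherx)
    expect_log_equal(run$events$dosing, ref$dosing)
    expect_log_equal(run$events$exchange, ref$exchange)
    expect_log_equal(run$events$use, ref$use)
    expect_log_equal(run$movement, ref$movement)
    ## end-of-run stores agree entry by entry
    fk <- run$final_knowledge
    for (i in seq_len(nrow(world$agents))) {
      st <- ref$stores[[i]]
      eng <- fk[agent_id == i][order(resource_id)]
      o <- order(st$res)
      expect_identical(eng$resource_id, st$res[o])
      expect_identical(eng$rx_derived, st$rx[o])
    }
  }
})

test_that("identical inputs and seed reproduce the run byte for byte", {
  world <- mini_world()
  pool <- mini_pool()
  r1 <- run_simulation(world, pool, mini_sim_config())
  r2 <- run_simulation(world, pool, mini_sim_config())
  expect_identical(r1$events, r2$events)
  expect_identical(r1$healtherx, r2$healtherx)
  expect_identical(r1$final_knowledge, r2$final_knowledge)
  r3 <- run_simulation(world, pool, {
    cfg <- mini_sim_config(); cfg$seed <- 12L; cfg
  })
  expect_false(identical(r1$events$exchange, r3$events$exchange))
})

test_that("a lone agent can never exchange information", {
  world <- mini_world(n_agents = 1L, activations = 0.9)
  pool <- mini_pool()
  run <- run_simulation(world, pool, {
    cfg <- mini_sim_config()
    cfg$initial_knowledge <- mini_kn()[agent_id == 1L]
    cfg
  })
  expect_identical(nrow(run$events$exchange), 0L)
  expect_identical(nrow(run$events$dosing[source == "Peer"]), 0L)
})

test_that("a 28-day run spans 672 hourly ticks", {
  world <- mini_world(n_agents = 2L)
  pool <- mini_pool()
  cfg <- simulation_config(n_days = 28L, seed = 3L,
                           initial_knowledge = mini_kn()[agent_id <= 2L],
                           log_movement = TRUE)
  run <- run_simulation(world, pool, cfg)
  expect_identical(sort(unique(run$movement$hour)), 0:671)
  expect_identical(names(run$snapshots), c("1", "2", "3", "4"))
  expect_true(all(run$events$exchange$burn_in == (run$events$exchange$hour < 336)))
})

test_that("exchange events join to co-location in the movement log", {
  world <- mini_world()
  pool <- mini_pool()
  run <- run_simulation(world, pool, mini_sim_config())
  ex <- run$events$exchange
  expect_gt(nrow(ex), 0L)
  mv <- run$movement
  gi <- mv[ex, on = c(hour = "hour", agent_id = "giver_id")]
  re <- mv[ex, on = c(hour = "hour", agent_id = "receiver_id")]
  expect_identical(gi$place_id, ex$place_id)
  expect_identical(re$place_id, ex$place_id)
})

test_that("every dose traces to its causal event", {
  world <- mini_world()
  pool <- mini_pool()
  run <- run_simulation(world, pool, mini_sim_config())
  dos <- run$events$dosing
  peers <- dos[source == "Peer"]
  ex <- run$events$exchange
  joined <- ex[peers, on = c(hour = "hour", giver_id = "giver_id",
                             receiver_id = "agent_id",
                             resource_id = "resource_id")]
  expect_false(anyNA(joined$place_id))
  clin <- dos[source %in% c("Doctor", "Nurse", "ClinicalStaff")]
  expect_true(all(clin$agent_id %in% run$events$visit$agent_id))
  expect_gt(nrow(clin), 0L)
})

test_that("zero propensity rates silence all exchange", {
  world <- mini_world()
  pool <- mini_pool(p_rates = c(none = 0, low = 0, medium = 0, high = 0))
  run <- run_simulation(world, pool, mini_sim_config())
  expect_identical(nrow(run$events$exchange), 0L)
})

test_that("decide_ab reproduces the threshold arithmetic", {
  world <- mini_world()
  ## craft a store with one fitness candidate: beta .8, known gamma .9
  world$resources$inertia[2] <- 0.9
  store <- data.table(resource_id = 2L, beta = 0.8, last_update = 0L,
                      rx_derived = FALSE)
  act <- mini_catalog()[code == "gym"]
  ## place the agent so that exp(-d/d0) = 0.8 => d = -2*log(0.8)
  d <- -2 * log(0.8)
  world$places$x[1] <- world$places$x[3]
  world$places$y[1] <- world$places$y[3] - d
  ag <- one_agent(activation = 0.5)
  out <- decide_ab(ag, act, store, world, decision_params(2.0), from_place = 1L)
  expect_identical(out$decision, "A")
  expect_equal(out$score, 0.8 * 0.8 * 0.9, tolerance = 1e-12)
  ag$activation <- 0.6
  out <- decide_ab(ag, act, store, world, decision_params(2.0), from_place = 1L)
  expect_identical(out$decision, "B")
  expect_equal(out$score, 0.576, tolerance = 1e-12)
})

test_that("decide_ab argmax agrees with exhaustive enumeration", {
  set.seed(42)
  for (rep in 1:20) {
    nr <- 10L
    places <- data.table(place_id = seq_len(nr + 1L),
                         kind = c("household", rep("resource_site", nr)),
                         x = runif(nr + 1, 0, 10), y = runif(nr + 1, 0, 10))
    resources <- data.table(resource_id = seq_len(nr),
                            place_id = seq_len(nr) + 1L,
                            service_type = "fitness",
                            inertia = runif(nr, 0.5, 1))
    world <- structure(list(agents = one_agent(), places = places,
                            resources = resources, frame = "planar_km",
                            bounding_box = c(0, 0, 10, 10), seed = NA,
                            config = NULL), class = "crx_world")
    store <- data.table(resource_id = seq_len(nr), beta = runif(nr),
                        last_update = 0L, rx_derived = FALSE)
    act <- mini_catalog()[code == "gym"]
    ag <- one_agent(activation = 0.2)
    out <- decide_ab(ag, act, store, world, decision_params(2.0),
                     from_place = 1L)
    ## brute force
    sc <- vapply(seq_len(nr), function(j) {
      d <- sqrt((places$x[1] - places$x[j + 1])^2 +
                  (places$y[1] - places$y[j + 1])^2)
      store$beta[j] * exp(-d / 2) * resources$inertia[j]
    }, 1)
    best <- which.max(sc)
    if (max(sc) > 0.2) {
      expect_identical(out$decision, "A")
      expect_identical(out$resource_id, best)
      expect_equal(out$score, sc[best], tolerance = 1e-12)
    } else {
      expect_identical(out$decision, "B")
    }
  }
})

test_that("decide_ab returns B for an empty candidate set", {
  world <- mini_world()
  act <- mini_catalog()[code == "gym"]
  out <- decide_ab(one_agent(), act, knowledge_store(), world)
  expect_identical(out$decision, "B")
  ## known resources, none of the mapped service
  store <- data.table(resource_id = 3L, beta = 0.99, last_update = 0L,
                      rx_derived = FALSE)
  out <- decide_ab(one_agent(), act, store, world)
  expect_identical(out$decision, "B")
})

test_that("assign_location resolves policies and falls back to home", {
  world <- mini_world()
  cata <- mini_catalog()
  ag <- world$agents[1]
  expect_identical(assign_location(ag, cata[code == "sleep"], world), 1L)
  ## work activity without a workplace: remapped to home
  work_act <- data.table(code = "work", location_policy = "work",
                         decision_type = "none", mapped_services = "")
  expect_identical(assign_location(ag, work_act, world), ag$household_id)
  ## scheduled medical care resolves to the clinic
  expect_identical(assign_location(ag, cata[code == "clinic_visit"], world), 2L)
})

test_that("out-of-home draws stay in radius and are roughly uniform", {
  cfgw <- small_world_config(50L)
  world <- generate_world(cfgw, seed = 7L)
  ag <- world$agents[1]
  act <- mini_catalog()[code == "out_social"]
  hrow <- world$places[match(ag$household_id, world$places$place_id)]
  cand <- world$places[kind != "household"]
  d <- coord_distance(hrow$x, hrow$y, cand$x, cand$y, "planar_km")
  inr <- sort(cand$place_id[d <= 5])
  set.seed(99)
  draws <- replicate(10000, assign_location(ag, act, world, radius_km = 5))
  expect_true(all(draws %in% inr))
  freq <- table(factor(draws, levels = inr)) / 10000
  expect_true(all(abs(freq - 1 / length(inr)) <
                    3 * sqrt((1 / length(inr)) / 10000) + 0.005))
})

test_that("exchange op: propensity gates, empty stores transmit nothing", {
  kn <- mini_kn()
  cfg <- simulation_config(seed = 1L)
  grp0 <- data.table(agent_id = c(1L, 3L), p = c(0, 0))
  out <- exchange(grp0, kn, cfg, place_id = 1L, t = 0L)
  expect_identical(nrow(out$events), 0L)
  ## p = 1 between two agents, top-beta policy
  set.seed(5)
  grp <- data.table(agent_id = c(1L, 2L), p = c(1, 1))
  out <- exchange(grp, kn, cfg, place_id = 1L, t = 0L)
  ## agent 2 has an empty store: receiver 1 logs an exchange, gains nothing
  ev1 <- out$events[receiver_id == 1L]
  expect_identical(nrow(ev1), 1L)
  expect_true(is.na(ev1$resource_id))
  ## receiver 2 gains giver 1's max-beta resource (resource 2 at beta .8)
  ev2 <- out$events[receiver_id == 2L]
  expect_identical(ev2$resource_id, 2L)
  expect_identical(out$doses$resource_id, 2L)
})

test_that("tracked beta trajectories jump at doses and decay in between", {
  world <- mini_world()
  pool <- mini_pool()
  cfg <- mini_sim_config(track = data.frame(agent_id = c(1L, 3L),
                                            resource_id = c(2L, 2L)))
  run <- run_simulation(world, pool, cfg)
  lam <- cfg$knowledge$lambda
  for (z in 1:2) {
    pair <- cfg$track[z, ]
    tr <- beta_trajectory(run, pair$agent_id, pair$resource_id)
    dose_hours <- run$events$dosing[agent_id == pair$agent_id &
                                      resource_id == pair$resource_id, hour]
    expect_gt(length(dose_hours), 0L)
    for (h in 1:(nrow(tr) - 1L)) {
      prev <- tr$beta[h]; cur <- tr$beta[h + 1L]
      if (is.na(prev) || is.na(cur)) next
      if ((h) %in% dose_hours) {       # hour index h corresponds to tick h
        expect_gt(cur, prev * lam - 1e-12)
      } else {
        expect_equal(cur, prev * lam, tolerance = 1e-9)
      }
    }
  }
})
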