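# Knowledge dynamics: the reinforcement update, decay, seeding and the
# capped store.

test_that("the reinforcement update matches its closed-form evaluation", {
  p <- knowledge_params()
  expect_equal(boost(0.5, "Doctor", p), 0.97862145098226105, tolerance = 1e-12)
  expect_equal(boost(0.5, "Nurse", p), 0.94656960422366643, tolerance = 1e-12)
  expect_equal(boost(0.5, "Peer", p), 0.76553187534336664, tolerance = 1e-12)
  expect_equal(boost(0.5, "ClinicalStaff", p), 0.91666417375821552,
               tolerance = 1e-12)
  expect_equal(boost(0.5, "Use", p), 0.93135780411322955, tolerance = 1e-12)
  expect_error(boost(0.5, "Stranger", p), "unknown dose source")
})

test_that("the update preserves [0,1] with fixed points at 0 and 1", {
  p <- knowledge_params()
  srcs <- names(dose_sources())
  for (s in srcs) {
    expect_identical(boost(0, s, p), 0)
    expect_identical(boost(1, s, p), 1)
  }
  set.seed(1)
  beta <- runif(10000)
  src <- sample(srcs, 10000, replace = TRUE)
  for (s in srcs) {
    sel <- src == s
    out <- boost(beta[sel], s, p)
    expect_true(all(out >= 0 & out <= 1))
    expect_true(all(out >= beta[sel]))
  }
})

test_that("stronger sources always boost harder", {
  p <- knowledge_params()
  set.seed(2)
  beta <- runif(1000, min = 1e-6, max = 1 - 1e-6)
  d <- boost(beta, "Doctor", p); nu <- boost(beta, "Nurse", p)
  cs <- boost(beta, "ClinicalStaff", p); pe <- boost(beta, "Peer", p)
  us <- boost(beta, "Use", p)
  expect_true(all(d > nu))
  expect_true(all(nu > cs))
  expect_true(all(cs > pe))
  expect_true(all(us > cs))
})

test_that("decay modes behave as configured", {
  p <- knowledge_params()
  expect_identical(decay_beta(0.5, 0, p), 0.5)
  expect_equal(decay_beta(0.5, 1, p), 0.4955, tolerance = 1e-12)
  pap <- knowledge_params(decay_mode = "as_printed")
  expect_identical(decay_beta(0.7, 0, pap), 0.7)
  ## the printed functional form with the None source grows
  expect_equal(decay_beta(0.5, 1, pap), 0.74775, tolerance = 1e-12)
  ## lazy geometric evaluation equals hour-by-hour application
  set.seed(3)
  for (dt_ in c(1L, 7L, 24L, 100L)) {
    b <- runif(1)
    step <- b
    for (i in seq_len(dt_)) step <- step * p$lambda
    expect_equal(decay_beta(b, dt_, p), step, tolerance = 1e-12)
  }
})

test_that("lambda outside the allowable range is rejected", {
  expect_error(knowledge_params(lambda = 0.9), "lambda")
  expect_error(knowledge_params(lambda = 0.9999), "lambda")
  expect_silent(knowledge_params(lambda = 0.9994))
})

test_that("seeding draws counts per distance stratum and clips to supply", {
  ## no resources -> empty store
  w0 <- mini_world()
  w0$resources <- w0$resources[0]
  expect_identical(nrow(seed_knowledge(one_agent(household_id = 1L), w0)), 0L)
  ## dense world: every resource in the low stratum, counts in [10, 100]
  cfg <- demographic_config(n_agents = 200L, bounding_box = c(0, 0, 1, 1),
                            n_households = 80L, n_workplaces = 5L,
                            n_schools = 1L, n_clinics = 2L,
                            n_resource_sites = 300L, services_per_site = 1L)
  w <- generate_world(cfg, seed = 4L)
  kn <- seed_world_knowledge(w)
  cnt <- kn[, .N, by = agent_id]
  expect_true(all(cnt$N >= 10 & cnt$N <= 100))
  ## standard-sized world: per-stratum counts within the configured ranges
  wb <- generate_world(small_world_config(100L), seed = 5L)
  sp <- seeding_params()
  knb <- seed_world_knowledge(wb, sp)
  pl <- wb$places
  for (i in sample(wb$agents$agent_id, 20L)) {
    st <- knb[agent_id == i]
    home <- pl[match(wb$agents$household_id[i], pl$place_id)]
    rp <- pl[match(wb$resources$place_id[match(st$resource_id,
                                               wb$resources$resource_id)],
                   pl$place_id)]
    d <- coord_distance(home$x, home$y, rp$x, rp$y, "planar_km")
    expect_lte(sum(d <= sp$low_radius_km), 100L)
    expect_lte(sum(d > sp$low_radius_km & d <= sp$mid_radius_km), 5L)
    expect_lte(sum(d > sp$mid_radius_km), 5L)
  }
  expect_true(all(knb$beta >= 0.1 & knb$beta <= 0.5))
  expect_true(all(!knb$rx_derived))
})

test_that("a stratum with fewer resources than the drawn count is clipped", {
  w <- mini_world()   # 2 resources at the site ~1 km away, 1 at the clinic
  sp <- seeding_params(low_radius_km = 1.7, mid_radius_km = 3,
                       low_count_range = c(5L, 5L))
  set.seed(6)
  st <- seed_knowledge(w$agents[1], w, sp)
  ## all 3 resources are within 1.7 km; only 3 can be seeded
  expect_identical(nrow(st), 3L)
})

test_that("upsert caps the store and always evicts the minimum", {
  p3 <- knowledge_params(capacity = 3L)
  st <- knowledge_store()
  st <- upsert(st, 10L, 0.4, params = p3)$store
  expect_identical(nrow(st), 1L)
  st <- upsert(st, 11L, 0.2, params = p3)$store
  st <- upsert(st, 12L, 0.6, params = p3)$store
  ## update in place, flag ORed
  st <- upsert(st, 10L, 0.9, rx_flag = TRUE, params = p3)$store
  expect_identical(nrow(st), 3L)
  expect_identical(st[resource_id == 10L, beta], 0.9)
  expect_true(st[resource_id == 10L, rx_derived])
  ## at capacity: higher beta evicts the current minimum (resource 11)
  out <- upsert(st, 13L, 0.5, params = p3)
  expect_identical(out$evicted, 11L)
  expect_identical(nrow(out$store), 3L)
  expect_false(11L %in% out$store$resource_id)
  ## at capacity: lower-or-equal beta is discarded
  out2 <- upsert(out$store, 14L, 0.5, params = p3)
  expect_null(out2$evicted)
  expect_false(14L %in% out2$store$resource_id)
  ## beta ties evict the lower resource id
  tie <- data.table::data.table(resource_id = c(1L, 2L, 3L),
                                beta = c(0.3, 0.3, 0.8),
                                last_update = 0L, rx_derived = FALSE)
  out3 <- upsert(tie, 9L, 0.5, params = p3)
  expect_identical(out3$evicted, 1L)
})

test_that("random upsert sequences keep every invariant", {
  p <- knowledge_params(capacity = 8L)
  set.seed(7)
  st <- knowledge_store()
  for (i in 1:400) {
    r <- sample.int(30L, 1L)
    b <- runif(1)
    pre <- data.table::copy(st)
    out <- upsert(st, r, b, rx_flag = runif(1) < 0.2, params = p)
    st <- out$store
    expect_lte(nrow(st), 8L)
    expect_true(all(st$beta >= 0 & st$beta <= 1))
    expect_identical(anyDuplicated(st$resource_id), 0L)
    if (!is.null(out$evicted)) {
      ## the eviction victim was a current minimum-beta entry
      expect_identical(pre[order(beta, resource_id), resource_id][1],
                       out$evicted)
    }
  }
})

test_that("dosing one agent with 500 resources never breaches capacity", {
  p <- knowledge_params()      # default capacity 200
  set.seed(8)
  st <- knowledge_store()
  for (r in sample(1:500)) {
    b <- boost(p$beta_init, "Doctor", p) * runif(1, 0.5, 1)
    st <- upsert(st, r, b, rx_flag = TRUE, params = p)$store
    expect_lte(nrow(st), 200L)
  }
  expect_identical(nrow(st), 200L)
})
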