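# Experiment pipelines: retainer classification, reach/delivery-mode
# pipelines, propensity sweeps and geographic export.

## three-agent fixture: A (clinic-goer) shares a household with B; C lives
## alone and can never be exposed
chain_world <- function() {
  places <- data.table::data.table(
    place_id = 1:4,
    kind = c("household", "household", "clinic", "resource_site"),
    x = c(1, 3, 2, 1), y = c(1, 3, 1, 2))
  resources <- data.table::data.table(
    resource_id = 1:2, place_id = c(3L, 4L),
    service_type = c("primary_care", "fitness"), inertia = c(0.9, 0.9))
  agents <- data.table::data.table(
    agent_id = 1:3, age = c(30L, 35L, 40L),
    sex = c("female", "male", "male"),
    race = "black", ethnicity = "non_hispanic",
    household_id = c(1L, 1L, 2L),
    workplace_id = NA_integer_, school_id = NA_integer_,
    preferred_language = NA_character_, conditions = "",
    activation = 0.95)
  structure(list(agents = agents, places = places, resources = resources,
                 frame = "planar_km", bounding_box = c(0, 0, 4, 4),
                 seed = NA_integer_, config = NULL),
            class = "crx_world")
}

chain_pool <- function(p_rates = c(none = 0, low = 0, medium = 1, high = 1),
                       with_clinic = TRUE) {
  cat <- mini_catalog()
  id <- function(code) cat$activity_id[match(code, cat$code)]
  female <- c(rep(id("sleep"), 6), id("chill"), id("social_home"),
              if (with_clinic) id("clinic_visit") else id("social_home"),
              rep(id("social_home"), 13), id("chill"), id("sleep"))
  male <- c(rep(id("sleep"), 6), id("chill"),
            rep(id("social_home"), 16), id("sleep"))
  hours <- rbind(female, female, male, male,   # weekday
                 female, female, male, male)   # weekend
  templates <- data.table::data.table(
    template_id = 1:8,
    age_band = c("16-30", "16-30", "31-45", "31-45",
                 "16-30", "16-30", "31-45", "31-45"),
    sex = rep(c("female", "female", "male", "male"), 2),
    race = "black", ethnicity = "non_hispanic",
    day_type = rep(c("weekday", "weekend"), each = 4))
  ## agent 3 (age 40) shares the male 31-45 stratum with agent 2
  idx <- split(templates$template_id,
               paste(templates$age_band, templates$sex, templates$race,
                     templates$ethnicity, templates$day_type, sep = "|"))
  structure(list(catalog = cat, templates = templates, hours = hours,
                 p_rates = p_rates, index = idx, config = NULL,
                 seed = NA_integer_),
            class = "crx_pool")
}

chain_kn <- function() {
  kn <- data.table::data.table(agent_id = 1L, resource_id = 2L, beta = 0.3,
                               last_update = 0L, rx_derived = FALSE)
  data.table::setkey(kn, agent_id, resource_id)
  kn
}

chain_cfg <- function(seed = 21L)
  simulation_config(n_days = 8L, burn_in_days = 1L, seed = seed,
                    initial_knowledge = chain_kn())

test_that("a hand-traced chain classifies one clinical and one social retainer", {
  run <- run_simulation(chain_world(), chain_pool(), chain_cfg())
  cls <- classify_retainers(run, week = 1L)
  expect_identical(cls$n_clinical, 1L)
  expect_identical(cls$n_social_only, 1L)
  expect_identical(cls$ratio, 1.0)
  ## the sets are disjoint and agent 3 is untouched
  snap <- run$snapshots[["1"]]
  retainers <- unique(snap[rx_derived == TRUE, agent_id])
  rx_agents <- unique(run$healtherx$agent_id)
  expect_length(intersect(setdiff(retainers, rx_agents), rx_agents), 0L)
  expect_false(3L %in% retainers)
  expect_identical(rx_agents, 1L)
})

test_that("no prescriptions means an undefined reach ratio", {
  run <- run_simulation(chain_world(), chain_pool(with_clinic = FALSE),
                        chain_cfg())
  cls <- classify_retainers(run, week = 1L)
  expect_identical(cls$n_clinical, 0L)
  expect_identical(cls$n_social_only, 0L)
  expect_true(is.na(cls$ratio))
})

test_that("disabling all sharing removes the social pathway entirely", {
  run <- run_simulation(chain_world(),
                        chain_pool(p_rates = c(none = 0, low = 0,
                                               medium = 0, high = 0)),
                        chain_cfg())
  cls <- classify_retainers(run, week = 1L)
  expect_identical(cls$n_clinical, 1L)
  expect_identical(cls$n_social_only, 0L)
})

test_that("burn-in length only flags events, never changes them", {
  cfg1 <- chain_cfg(); cfg3 <- chain_cfg(); cfg3$burn_in_days <- 3L
  r1 <- run_simulation(chain_world(), chain_pool(), cfg1)
  r3 <- run_simulation(chain_world(), chain_pool(), cfg3)
  strip <- function(tb) { tb <- data.table::copy(tb); tb[, burn_in := NULL]; tb }
  expect_identical(strip(r1$events$exchange), strip(r3$events$exchange))
  expect_identical(strip(r1$events$dosing), strip(r3$events$dosing))
  expect_false(identical(r1$events$dosing$burn_in, r3$events$dosing$burn_in))
})

small_plan <- function(n_agents = 300L, replicates = 2L, seed = 5L, ...) {
  experiment_plan(
    world_config = small_world_config(n_agents),
    schedule_cfg = schedule_config(),
    sim_config = simulation_config(n_days = 8L, burn_in_days = 1L, ...),
    replicates = replicates, week = 1L, seed = seed)
}

test_that("the reach pipeline reports one row per replicate, reproducibly", {
  plan <- small_plan(replicates = 2L)
  out <- dosing_reach_experiment(plan)
  expect_identical(nrow(out$results), 2L)
  expect_true(all(out$results$n_clinical + out$results$n_social_only <=
                    nrow(out$world$agents)))
  out2 <- dosing_reach_experiment(plan)
  expect_identical(out$results, out2$results)
  ## one replicate: mean equals the single ratio
  one <- dosing_reach_experiment(small_plan(replicates = 1L))
  expect_identical(one$summary$mean_ratio, one$results$ratio)
})

test_that("raising the propensity rates never shrinks social-only reach", {
  plan <- small_plan(replicates = 1L)
  env <- crxsim:::plan_world(plan)
  lo <- crxsim:::plan_run(plan, env, 1L, list(p_rate_multiplier = 0.5))
  hi <- crxsim:::plan_run(plan, env, 1L, list(p_rate_multiplier = 2))
  expect_gte(classify_retainers(hi, 1L)$n_social_only,
             classify_retainers(lo, 1L)$n_social_only)
})

test_that("delivery-mode bookkeeping tags each run and handles silence", {
  plan <- small_plan(n_agents = 150L, replicates = 1L)
  out <- delivery_mode_experiment(plan)
  expect_identical(nrow(out$results), 3L)
  expect_setequal(out$results$delivery_mode, c("physician", "nurse", "clerk"))
  ## sharing disabled: all modes are trivially similar at zero social reach
  plan0 <- small_plan(n_agents = 150L, replicates = 1L,
                      p_rates = c(none = 0, low = 0, medium = 0, high = 0))
  out0 <- delivery_mode_experiment(plan0)
  expect_true(all(out0$results$n_social_only == 0L))
})

test_that("a zero multiplier produces empty networks at every replicate", {
  plan <- small_plan(n_agents = 150L, replicates = 2L)
  sweep <- pscore_sweep(plan, multipliers = c(off = 0, on = 1))
  expect_true(all(sweep$results[level == "off", n_edges] == 0L))
  expect_true(all(sweep$results[level == "on", n_edges] > 0L))
})

test_that("retainer geography is exported as consistent point sets", {
  run <- run_simulation(chain_world(), chain_pool(), chain_cfg())
  dir <- file.path(tempdir(), "geo")
  paths <- export_geography(run, chain_world(), dir, week = 1L)
  clin <- data.table::fread(paths$clinical[["csv"]])
  soc <- data.table::fread(paths$social_only[["csv"]])
  cls <- classify_retainers(run, week = 1L)
  expect_identical(nrow(clin), cls$n_clinical)
  expect_identical(nrow(soc), cls$n_social_only)
  w <- chain_world()
  hh <- w$places[match(w$agents$household_id[soc$agent_id], w$places$place_id)]
  expect_equal(soc$x, as.numeric(hh$x))
  gj <- jsonlite::read_json(paths$clinical[["geojson"]])
  expect_identical(gj$type, "FeatureCollection")
  expect_length(gj$features, cls$n_clinical)
  ## zero retainers: empty files with headers
  run0 <- run_simulation(chain_world(), chain_pool(with_clinic = FALSE),
                         chain_cfg())
  paths0 <- export_geography(run0, chain_world(), file.path(tempdir(), "geo0"),
                             week = 1L)
  empty <- data.table::fread(paths0$clinical[["csv"]])
  expect_identical(nrow(empty), 0L)
  expect_setequal(names(empty), c("agent_id", "x", "y"))
})
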