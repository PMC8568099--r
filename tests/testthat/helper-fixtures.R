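# Shared fixtures: a hand-sized world/pool whose every state transition can
# be traced by hand or by the straight-line reference simulator.

library(data.table)

## a compact activity catalog covering every location policy and decision
## type the engine knows about
mini_catalog <- function() {
  dt <- data.table::rbindlist(list(
    list("sleep",        "Sleeping",        "daily_living",       "none",   "none", "home",         "",             FALSE),
    list("social_home",  "Socializing",     "daily_living",       "medium", "none", "home",         "",             FALSE),
    list("out_social",   "Out socializing", "daily_living",       "medium", "none", "out_of_home",  "",             FALSE),
    list("clinic_visit", "Medical care",    "health_maintenance", "high",   "none", "service_site", "primary_care", TRUE),
    list("gym",          "Fitness",         "health_maintenance", "medium", "AB",   "service_site", "fitness",      FALSE),
    list("chill",        "Relaxing",        "daily_living",       "low",    "none", "home",         "",             FALSE)
  ))
  setnames(dt, c("code", "label", "activity_class", "p_level", "decision_type",
                 "location_policy", "mapped_services", "clinic_trigger"))
  dt[, activity_id := seq_len(.N)]
  setcolorder(dt, "activity_id")
  dt[]
}

## 5 agents in one household, one clinic, one resource site (3 places)
mini_world <- function(n_agents = 5L, activations = c(0.05, 0.9, 0.9, 0.9, 0.9)) {
  places <- data.table(place_id = 1:3,
                       kind = c("household", "clinic", "resource_site"),
                       x = c(1, 2, 1), y = c(1, 1, 2))
  resources <- data.table(resource_id = 1:3,
                          place_id = c(2L, 3L, 3L),
                          service_type = c("primary_care", "fitness",
                                           "spiritual_services"),
                          inertia = c(0.9, 0.9, 0.8))
  agents <- data.table(
    agent_id = seq_len(n_agents),
    age = c(25L, 27L, 28L, 29L, 30L)[seq_len(n_agents)],
    sex = "female", race = "black", ethnicity = "non_hispanic",
    household_id = 1L, workplace_id = NA_integer_, school_id = NA_integer_,
    preferred_language = NA_character_, conditions = "",
    activation = activations[seq_len(n_agents)])
  structure(list(agents = agents, places = places, resources = resources,
                 frame = "planar_km", bounding_box = c(0, 0, 4, 4),
                 seed = NA_integer_, config = NULL),
            class = "crx_world")
}

## schedule pool: one stratum, two templates per day type
mini_pool <- function(p_rates = c(none = 0, low = 0.1, medium = 0.5, high = 0.9)) {
  cat <- mini_catalog()
  id <- function(code) cat$activity_id[match(code, cat$code)]
  t1 <- c(rep(id("sleep"), 6), id("chill"), id("social_home"),
          id("clinic_visit"), id("gym"), id("out_social"), id("out_social"),
          rep(id("social_home"), 10), id("chill"), id("sleep"))
  t2 <- c(rep(id("sleep"), 6), id("chill"), id("chill"),
          rep(id("social_home"), 8), id("out_social"), id("out_social"),
          id("gym"), rep(id("social_home"), 3), id("chill"), id("sleep"))
  t3 <- c(rep(id("sleep"), 7), rep(id("social_home"), 6),
          rep(id("out_social"), 3), rep(id("social_home"), 6),
          id("chill"), id("sleep"))
  t4 <- c(rep(id("sleep"), 7), rep(id("chill"), 4), id("gym"),
          rep(id("social_home"), 10), id("chill"), id("sleep"))
  hours <- rbind(t1, t2, t3, t4)
  templates <- data.table(template_id = 1:4, age_band = "16-30",
                          sex = "female", race = "black",
                          ethnicity = "non_hispanic",
                          day_type = c("weekday", "weekday",
                                       "weekend", "weekend"))
  idx <- split(templates$template_id,
               paste(templates$age_band, templates$sex, templates$race,
                     templates$ethnicity, templates$day_type, sep = "|"))
  structure(list(catalog = cat, templates = templates, hours = hours,
                 p_rates = p_rates, index = idx, config = NULL,
                 seed = NA_integer_),
            class = "crx_pool")
}

## initial knowledge used by the engine-vs-reference comparisons
mini_kn <- function() {
  kn <- data.table(
    agent_id = c(1L, 1L, 3L, 4L, 5L, 5L),
    resource_id = c(2L, 3L, 2L, 3L, 2L, 3L),
    beta = c(0.8, 0.3, 0.2, 0.4, 0.5, 0.1),
    last_update = 0L, rx_derived = FALSE)
  setkey(kn, agent_id, resource_id)
  kn
}

## a reduced-size generated world for integration tests
small_world_config <- function(n_agents = 400L) {
  demographic_config(n_agents = n_agents,
                     n_workplaces = 40L, n_schools = 4L, n_clinics = 3L,
                     n_resource_sites = 60L)
}

## build a one-row agent for unit tests
one_agent <- function(age = 40L, sex = "female", household_id = 1L,
                      activation = 0.5, conditions = "") {
  data.table(agent_id = 1L, age = as.integer(age), sex = sex, race = "black",
             ethnicity = "non_hispanic", household_id = household_id,
             workplace_id = NA_integer_, school_id = NA_integer_,
             preferred_language = NA_character_, conditions = conditions,
             activation = activation)
}
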