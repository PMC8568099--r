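# In-silico resource-prescription (HealtheRx) generation and delivery:
# condition assignment, condition -> service indication, nearest-resource
# matching into 40-item lists, and delivery-mode-specific clinical dosing.

#' Default synthetic condition catalog
#'
#' Roughly ten common health and social conditions with age-graded (and for
#' depression, sex-specific) prevalences and the service types each
#' condition indicates. A synthetic stand-in for a clinical indication
#' catalog spanning common chronic conditions, social conditions and
#' statuses.
#'
#' @return data.table with columns `condition_code`, `age_band`
#'   (`16-30`/`31-45`/`46-65`/`66-94`), `sex` (`any`, `female`, `male`),
#'   `prevalence`, `services` (`;`-separated)
#' @export
condition_catalog_default <- function() {
  long <- function(code, prev, services, sex = "any") {
    data.table(condition_code = code, age_band = age_band_labels,
               sex = sex, prevalence = prev, services = services)
  }
  data.table::rbindlist(list(
    long("diabetes",            c(.03, .08, .17, .25), "fresh_produce;weight_management;fitness"),
    long("hypertension",        c(.05, .15, .35, .55), "fresh_produce;walking_group"),
    long("obesity",             c(.20, .30, .35, .30), "weight_management;group_exercise;fresh_produce"),
    long("depression",          c(.18, .15, .12, .10), "mental_health;spiritual_services", sex = "female"),
    long("depression",          c(.10, .08, .07, .06), "mental_health;spiritual_services", sex = "male"),
    long("smoking",             c(.15, .18, .15, .08), "smoking_cessation"),
    long("food_insecurity",     c(.25, .20, .15, .12), "food_pantry;fresh_produce"),
    long("housing_instability", c(.15, .10, .06, .04), "housing_support"),
    long("asthma",              c(.10, .08, .07, .06), "smoking_cessation;home_care"),
    long("arthritis",           c(.02, .07, .25, .45), "walking_group;senior_services"),
    long("social_isolation",    c(.05, .05, .08, .20), "spiritual_services;senior_services;group_exercise")
  ))
}

#' Age-status base service indications
#'
#' Every agent is indicated a small base service set by age status, so a
#' HealtheRx is never empty even for agents with no recorded conditions;
#' agents 66+ additionally receive senior-oriented services.
#' @param band age band label(s)
#' @return list of character service vectors (one per input band)
#' @export
status_services <- function(band) {
  lapply(band, function(b) {
    s <- c("fitness", "fresh_produce", "spiritual_services")
    if (b == "66-94") s <- c(s, "senior_services", "walking_group")
    s
  })
}

#' Assign conditions and preferred language to agents
#'
#' Independent Bernoulli draws per (agent, condition) at the prevalence of
#' the agent's (age band, sex) stratum; rows with `sex = "any"` apply to
#' both sexes. Languages are a weighted draw.
#'
#' @param agents agent table (modified copy returned)
#' @param catalog a condition catalog ([condition_catalog_default()])
#' @param language_weights named positive weights
#' @return agents with `conditions` (`;`-joined codes, `""` if none) and
#'   `preferred_language` filled
#' @export
assign_conditions <- function(agents, catalog = condition_catalog_default(),
                              language_weights = c(english = 0.85,
                                                   spanish = 0.10,
                                                   other = 0.05)) {
  if (nrow(catalog) == 0L) abort_config("empty condition catalog")
  if (any(catalog$prevalence < 0 | catalog$prevalence > 1))
    abort_config("prevalences must lie in [0, 1]")
  agents <- copy(as.data.table(agents))
  n <- nrow(agents)
  band <- as.character(age_band(agents$age))
  codes <- unique(catalog$condition_code)
  has <- matrix(FALSE, n, length(codes), dimnames = list(NULL, codes))
  for (ci in seq_along(codes)) {
    sub <- catalog[condition_code == codes[ci]]
    prev <- rep(0, n)
    for (r in seq_len(nrow(sub))) {
      sel <- band == sub$age_band[r] &
        (sub$sex[r] == "any" | agents$sex == sub$sex[r])
      prev[sel] <- sub$prevalence[r]
    }
    has[, ci] <- runif(n) < prev
  }
  agents[, conditions := apply(has, 1L, function(z) paste(codes[z], collapse = ";"))]
  agents[, preferred_language := sample(names(language_weights), n,
                                        replace = TRUE, prob = language_weights)]
  agents[]
}

#' Services indicated for an agent
#'
#' Union of the age-status base set and the services indicated by each of
#' the agent's conditions, sorted alphabetically.
#' @param agent one-row agent table (with `conditions` filled or NA)
#' @param catalog condition catalog
#' @return character vector of service types
#' @export
indicated_services <- function(agent, catalog = condition_catalog_default()) {
  base <- status_services(as.character(age_band(agent$age)))[[1]]
  conds <- agent$conditions
  extra <- character()
  if (!is.na(conds) && nzchar(conds)) {
    codes <- strsplit(conds, ";", fixed = TRUE)[[1]]
    svc <- unique(catalog[condition_code %in% codes, services])
    extra <- unlist(strsplit(svc, ";", fixed = TRUE))
  }
  sort(unique(c(base, extra)))
}

#' Generate a personalized resource prescription (HealtheRx)
#'
#' Deterministic matching of an agent to up to 40 resources: the indicated
#' service types are collected from the agent's conditions and age status;
#' for each indicated service the resources nearest the agent's household
#' are listed nearest-first; the final list is filled round-robin across
#' the indicated services (first-nearest of each service, then
#' second-nearest, ...), de-duplicated, and truncated at `max_items`.
#'
#' @param agent one-row agent table
#' @param clinic a place row of kind `clinic`
#' @param world a `crx_world`
#' @param catalog condition catalog
#' @param max_items list size cap (default 40)
#' @return a `crx_healtherx` list: `agent_id`, `clinic_id`, `items`
#'   (ordered resource ids), `services` (the indicated services); `rx_id`,
#'   `hour` and `delivery_mode` are filled at delivery time
#' @export
generate_healtherx <- function(agent, clinic, world,
                               catalog = condition_catalog_default(),
                               max_items = 40L) {
  if (!identical(clinic$kind, "clinic"))
    abort_config("HealtheRx must be issued at a place of kind 'clinic'")
  svcs <- indicated_services(agent, catalog)
  home <- world$places[match(agent$household_id, world$places$place_id)]
  per_svc <- lapply(svcs, function(s)
    nearest_resources(world, home, s, max_items)$resource_id)
  items <- integer(0)
  depth <- if (length(per_svc)) max(lengths(per_svc)) else 0L
  for (rank in seq_len(depth)) {
    for (v in per_svc) if (rank <= length(v)) items <- c(items, v[rank])
    if (length(unique(items)) >= max_items) break
  }
  items <- unique(items)
  if (length(items) > max_items) items <- items[seq_len(max_items)]
  structure(list(rx_id = NA_integer_, agent_id = agent$agent_id,
                 clinic_id = clinic$place_id, hour = NA_integer_,
                 delivery_mode = NA_character_, items = items,
                 services = svcs),
            class = "crx_healtherx")
}

#' Delivery configuration
#'
#' Maps the clinical delivery mode to the dose source used for every item
#' of a delivered HealtheRx, and names the clinic-visit trigger activities.
#' @param delivery_mode `"physician"`, `"nurse"` or `"clerk"`
#' @param trigger_codes activity codes that issue a HealtheRx when
#'   performed at a clinic (at most one per agent per simulated day)
#' @return `crx_delivery_config` list
#' @export
delivery_config <- function(delivery_mode = c("physician", "nurse", "clerk"),
                            trigger_codes = c("medical_care_self",
                                              "medical_care_hh")) {
  delivery_mode <- match.arg(delivery_mode)
  map <- c(physician = "Doctor", nurse = "Nurse", clerk = "ClinicalStaff")
  structure(list(delivery_mode = delivery_mode,
                 dose_source = unname(map[delivery_mode]),
                 mode_sources = map,
                 trigger_codes = trigger_codes),
            class = "crx_delivery_config")
}

#' Deliver a HealtheRx to an agent's knowledge store
#'
#' Applies one boost per listed resource with the delivery mode's dose
#' source, marks each touched entry as HealtheRx-derived, and returns one
#' dosing event per item. Entries are decayed to the delivery hour before
#' boosting; unknown resources enter at `params$beta_init` before their
#' boost.
#'
#' @param rx a `crx_healtherx`
#' @param store the agent's knowledge store
#' @param cfg [delivery_config()]
#' @param params [knowledge_params()]
#' @param t delivery hour
#' @return list with updated `store` and an `events` data.table
#'   (`hour`, `agent_id`, `resource_id`, `source`, `rank`, `beta_after`)
#' @export
deliver <- function(rx, store, cfg = delivery_config(),
                    params = knowledge_params(), t = 0L) {
  src <- cfg$dose_source
  n <- length(rx$items)
  beta_after <- numeric(n)
  for (i in seq_len(n)) {
    r <- rx$items[i]
    j <- match(r, store$resource_id)
    b0 <- if (is.na(j)) params$beta_init
          else decay_beta(store$beta[j], t - store$last_update[j], params)
    b1 <- boost(b0, src, params)
    store <- upsert(store, r, b1, rx_flag = TRUE, params = params, t = t)$store
    beta_after[i] <- b1
  }
  events <- data.table(hour = as.integer(t), agent_id = rx$agent_id,
                       resource_id = rx$items, source = src,
                       rank = seq_len(n), beta_after = beta_after)
  list(store = store, events = events)
}
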