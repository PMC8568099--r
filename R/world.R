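# World generation: synthetic agents, places and resources on a planar or
# geographic coordinate frame.

#' Demographic configuration for the synthetic world
#'
#' Describes the marginal distributions and entity counts used by
#' [generate_world()]. Defaults are a desk-scale stand-in for a large urban
#' study region: a 16 km x 16 km planar box, a majority-female population
#' (56%) with mean age close to 44 years (ages 16--94), and uniformly placed
#' households, workplaces, schools, clinics and resource sites.
#'
#' Ages are drawn uniformly within four bands (16--30, 31--45, 46--65,
#' 66--94) with weights 0.30 / 0.28 / 0.27 / 0.15; the implied mean age is
#' 0.30*23 + 0.28*38 + 0.27*55.5 + 0.15*80 = 44.5 years, inside the
#' 44 +/- 1 design window.
#'
#' @param n_agents number of agents (>= 0)
#' @param sex_proportions named fractions summing to 1
#' @param ethnicity_proportions named fractions summing to 1
#' @param race_proportions named fractions summing to 1
#' @param age_band_weights fractions for bands 16-30, 31-45, 46-65, 66-94
#' @param bounding_box numeric `c(xmin, ymin, xmax, ymax)`; km in the
#'   `planar_km` frame, lon/lat degrees in `wgs84`
#' @param coordinate_frame `"planar_km"` or `"wgs84"`
#' @param n_households,n_workplaces,n_schools,n_clinics,n_resource_sites
#'   entity counts
#' @param services_per_site integer vector sampled uniformly for the number
#'   of distinct services offered at each resource site
#' @param service_types controlled vocabulary of non-clinic service types
#' @param employment_rate probability that an agent aged 16--65 is assigned
#'   a workplace (uniformly at random among workplaces)
#' @param school_age upper age (inclusive) for school assignment
#' @param activation_shape1,activation_shape2 Beta parameters for the agent
#'   activation threshold alpha
#' @param inertia_range uniform range for resource inertia gamma
#' @return a `crx_demographic_config` list
#' @export
demographic_config <- function(n_agents = 10000L,
                               sex_proportions = c(female = 0.56, male = 0.44),
                               ethnicity_proportions = c(non_hispanic = 0.84,
                                                         hispanic = 0.16),
                               race_proportions = c(black = 0.59, white = 0.25,
                                                    other = 0.16),
                               age_band_weights = c(`16-30` = 0.30,
                                                    `31-45` = 0.28,
                                                    `46-65` = 0.27,
                                                    `66-94` = 0.15),
                               bounding_box = c(0, 0, 16, 16),
                               coordinate_frame = c("planar_km", "wgs84"),
                               n_households = max(1L, round(n_agents / 2.5)),
                               n_workplaces = 300L,
                               n_schools = 20L,
                               n_clinics = 10L,
                               n_resource_sites = 250L,
                               services_per_site = 1:4,
                               service_types = default_service_types(),
                               employment_rate = 0.6,
                               school_age = 18L,
                               activation_shape1 = 2,
                               activation_shape2 = 2,
                               inertia_range = c(0.5, 1.0)) {
  coordinate_frame <- match.arg(coordinate_frame)
  if (n_agents < 0) abort_config("n_agents must be >= 0")
  check_proportions(sex_proportions, "sex_proportions")
  check_proportions(ethnicity_proportions, "ethnicity_proportions")
  check_proportions(race_proportions, "race_proportions")
  check_proportions(age_band_weights, "age_band_weights")
  if (length(bounding_box) != 4 ||
      bounding_box[3] <= bounding_box[1] || bounding_box[4] <= bounding_box[2])
    abort_config("bounding_box must be c(xmin, ymin, xmax, ymax) with positive extent")
  structure(list(
    n_agents = as.integer(n_agents),
    sex_proportions = sex_proportions,
    ethnicity_proportions = ethnicity_proportions,
    race_proportions = race_proportions,
    age_band_weights = age_band_weights,
    bounding_box = bounding_box,
    coordinate_frame = coordinate_frame,
    n_households = as.integer(n_households),
    n_workplaces = as.integer(n_workplaces),
    n_schools = as.integer(n_schools),
    n_clinics = as.integer(n_clinics),
    n_resource_sites = as.integer(n_resource_sites),
    services_per_site = as.integer(services_per_site),
    service_types = service_types,
    employment_rate = employment_rate,
    school_age = as.integer(school_age),
    activation_shape1 = activation_shape1,
    activation_shape2 = activation_shape2,
    inertia_range = inertia_range
  ), class = "crx_demographic_config")
}

#' Default controlled vocabulary of service types
#'
#' `primary_care` is offered at clinics only; the remaining types at
#' resource sites.
#' @return character vector of service type labels
#' @export
default_service_types <- function() {
  c("fitness", "group_exercise", "walking_group", "spiritual_services",
    "fresh_produce", "food_pantry", "smoking_cessation", "weight_management",
    "mental_health", "housing_support", "senior_services", "home_care")
}

place_kinds <- c("household", "workplace", "school", "clinic", "resource_site")

#' Generate a synthetic world
#'
#' Draws agents with demographic attributes and an activation threshold
#' `alpha ~ Beta(shape1, shape2)`, assigns each a household, a workplace
#' (working-age agents, at `employment_rate`) and a school (agents up to
#' `school_age`), and places all entities uniformly in the bounding box.
#' Every clinic offers a `primary_care` resource; each resource site offers
#' a uniform draw of distinct service types, each with inertia
#' `gamma ~ Uniform(inertia_range)`.
#'
#' The generation is a pure function of `(config, seed)`: regenerating with
#' the same seed is identical.
#'
#' @param config a [demographic_config()]
#' @param seed integer RNG seed
#' @return a `crx_world` list with data.tables `agents`, `places`,
#'   `resources`, plus `frame`, `bounding_box`, `seed` and the config echo
#' @export
generate_world <- function(config = demographic_config(), seed = 1L) {
  stopifnot(inherits(config, "crx_demographic_config"))
  set.seed(seed)
  n <- config$n_agents
  bb <- config$bounding_box

  ## places first: they exist even for an empty population
  n_places <- config$n_households + config$n_workplaces + config$n_schools +
    config$n_clinics + config$n_resource_sites
  kind <- rep(place_kinds, times = c(config$n_households, config$n_workplaces,
                                     config$n_schools, config$n_clinics,
                                     config$n_resource_sites))
  places <- data.table(
    place_id = seq_len(n_places),
    kind = kind,
    x = runif(n_places, bb[1], bb[3]),
    y = runif(n_places, bb[2], bb[4])
  )

  ## resources: primary_care at every clinic, then site services
  clinic_ids <- places[kind == "clinic", place_id]
  site_ids <- places[kind == "resource_site", place_id]
  svc_list <- lapply(site_ids, function(p) {
    k <- resample(config$services_per_site, 1L)
    sort(resample(config$service_types, min(k, length(config$service_types))))
  })
  resources <- data.table(
    place_id = c(clinic_ids, rep(site_ids, lengths(svc_list))),
    service_type = c(rep("primary_care", length(clinic_ids)),
                     unlist(svc_list))
  )
  resources[, resource_id := seq_len(.N)]
  resources[, inertia := runif(.N, config$inertia_range[1], config$inertia_range[2])]
  setcolorder(resources, c("resource_id", "place_id", "service_type", "inertia"))

  ## agents
  if (n > 0) {
    band_breaks <- list(`16-30` = 16:30, `31-45` = 31:45,
                        `46-65` = 46:65, `66-94` = 66:94)
    band_draw <- sample(names(config$age_band_weights), n, replace = TRUE,
                        prob = config$age_band_weights)
    age <- vapply(band_draw, function(b) resample(band_breaks[[b]], 1L), 1L)
    sex <- sample(names(config$sex_proportions), n, replace = TRUE,
                  prob = config$sex_proportions)
    race <- sample(names(config$race_proportions), n, replace = TRUE,
                   prob = config$race_proportions)
    ethnicity <- sample(names(config$ethnicity_proportions), n, replace = TRUE,
                        prob = config$ethnicity_proportions)
    hh_ids <- places[kind == "household", place_id]
    household <- hh_ids[sample.int(length(hh_ids), n, replace = TRUE)]
    wp_ids <- places[kind == "workplace", place_id]
    employed <- age <= 65 & runif(n) < config$employment_rate
    workplace <- rep(NA_integer_, n)
    if (length(wp_ids) && any(employed))
      workplace[employed] <- wp_ids[sample.int(length(wp_ids), sum(employed),
                                               replace = TRUE)]
    sc_ids <- places[kind == "school", place_id]
    in_school <- age <= config$school_age
    school <- rep(NA_integer_, n)
    if (length(sc_ids) && any(in_school))
      school[in_school] <- sc_ids[sample.int(length(sc_ids), sum(in_school),
                                             replace = TRUE)]
    activation <- rbeta(n, config$activation_shape1, config$activation_shape2)
    agents <- data.table(
      agent_id = seq_len(n),
      age = as.integer(age),
      sex = sex, race = race, ethnicity = ethnicity,
      household_id = household,
      workplace_id = workplace,
      school_id = school,
      preferred_language = NA_character_,
      conditions = NA_character_,
      activation = activation
    )
  } else {
    agents <- data.table(
      agent_id = integer(), age = integer(), sex = character(),
      race = character(), ethnicity = character(), household_id = integer(),
      workplace_id = integer(), school_id = integer(),
      preferred_language = character(), conditions = character(),
      activation = numeric()
    )
  }

  structure(list(agents = agents, places = places, resources = resources,
                 frame = config$coordinate_frame,
                 bounding_box = bb, seed = as.integer(seed), config = config),
            class = "crx_world")
}

#' @export
print.crx_world <- function(x, ...) {
  cat(sprintf("<crx_world> %d agents, %d places, %d resources (%s frame, seed %d)\n",
              nrow(x$agents), nrow(x$places), nrow(x$resources), x$frame, x$seed))
  invisible(x)
}

#' Distance between two places
#'
#' Euclidean in the `planar_km` frame; haversine great-circle distance
#' (Earth radius 6371 km) in `wgs84`, where coordinates are (lon, lat)
#' degrees. Both places must share a frame.
#'
#' @param x1,y1,x2,y2 coordinates (vectorized)
#' @param frame `"planar_km"` or `"wgs84"`
#' @return distance in kilometers
#' @export
coord_distance <- function(x1, y1, x2, y2, frame = "planar_km") {
  if (frame == "planar_km") {
    sqrt((x1 - x2)^2 + (y1 - y2)^2)
  } else if (frame == "wgs84") {
    rad <- pi / 180
    dlat <- (y2 - y1) * rad
    dlon <- (x2 - x1) * rad
    a <- sin(dlat / 2)^2 + cos(y1 * rad) * cos(y2 * rad) * sin(dlon / 2)^2
    2 * 6371 * asin(pmin(1, sqrt(a)))
  } else {
    abort_config("unknown coordinate frame '%s'", frame)
  }
}

#' Distance between two places of a world
#'
#' @param a,b single rows of a `places` table (or lists with `x`, `y`, and
#'   optionally `frame`)
#' @param frame coordinate frame; both places must share it
#' @return kilometers (symmetric, non-negative)
#' @export
place_distance <- function(a, b, frame = NULL) {
  fa <- a$frame %||% frame
  fb <- b$frame %||% frame
  if (is.null(fa) || is.null(fb)) abort_config("coordinate frame not specified")
  if (!identical(fa, fb))
    abort_config("places are in different coordinate frames ('%s' vs '%s')", fa, fb)
  coord_distance(a$x, a$y, b$x, b$y, fa)
}

#' Nearest resources of a service type
#'
#' Returns up to `k` resources providing `service_type`, ordered by
#' ascending distance from `origin`, ties broken by `resource_id`. An
#' unknown service type yields an empty result, not an error.
#'
#' @param world a `crx_world`
#' @param origin a place row (or list with `x`, `y`)
#' @param service_type service label
#' @param k maximum number of resources (>= 0)
#' @return data.table of resources with a `distance_km` column
#' @export
nearest_resources <- function(world, origin, service_type, k) {
  stopifnot(k >= 0)
  svc <- service_type
  res <- world$resources[world$resources[["service_type"]] == svc]
  if (nrow(res) == 0L || k == 0L) return(res[0][, distance_km := numeric(0)][])
  pl <- world$places[match(res$place_id, world$places$place_id)]
  d <- coord_distance(origin$x, origin$y, pl$x, pl$y, world$frame)
  out <- copy(res)[, distance_km := d]
  out <- out[order(distance_km, resource_id)]
  head(out, k)
}

#' Check referential integrity of a world
#'
#' Asserts that every agent's household (and any workplace/school) and every
#' resource's place resolve, that resource places are clinics or resource
#' sites, and that (place, service) pairs are unique.
#' @param world a `crx_world`
#' @return `TRUE` invisibly; stops on violation
#' @export
validate_world <- function(world) {
  p <- world$places
  a <- world$agents
  r <- world$resources
  stopifnot(all(a$household_id %in% p[kind == "household", place_id]))
  stopifnot(all(stats::na.omit(a$workplace_id) %in% p[kind == "workplace", place_id]))
  stopifnot(all(stats::na.omit(a$school_id) %in% p[kind == "school", place_id]))
  stopifnot(all(r$place_id %in% p$place_id))
  rk <- p$kind[match(r$place_id, p$place_id)]
  stopifnot(all(rk %in% c("clinic", "resource_site")))
  stopifnot(anyDuplicated(r[, .(place_id, service_type)]) == 0L)
  stopifnot(nrow(a) == 0L || (min(a$age) >= 16 && max(a$age) <= 94))
  stopifnot(all(a$activation > 0 & a$activation < 1))
  stopifnot(all(r$inertia > 0 & r$inertia <= 1))
  invisible(TRUE)
}
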