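# Activity catalog, synthetic 24-hour schedule pools, demographic matching,
# p-score assignment and service-exposure summaries.

#' Default activity catalog
#'
#' A ~20-activity stand-in for a time-use-survey activity list, classified
#' into daily-living versus health-maintenance activities, with an
#' information-receipt propensity level (`p_level`), a decision type
#' (health-maintenance activities mapped to resource services face an A/B
#' use decision; the scheduled medical-care activities instead trigger a
#' clinic visit), a location policy and a `;`-separated set of mapped
#' service types. `sleeping` has propensity `none` (no information is
#' received while asleep); `grocery_shopping` and `helping_hh_adults` are
#' `medium`; `work_social` and the medical-care activities are `high`.
#'
#' An editable copy ships as `inst/extdata/activities.csv`.
#'
#' @return data.table with columns `activity_id`, `code`, `label`,
#'   `activity_class`, `p_level`, `decision_type`, `location_policy`,
#'   `mapped_services`, `clinic_trigger`
#' @export
default_activity_catalog <- function() {
  dt <- data.table::rbindlist(list(
    list("sleeping",           "Sleeping",                         "daily_living",       "none",   "none", "home",         "",                                   FALSE),
    list("grooming",           "Washing and grooming",             "daily_living",       "none",   "none", "home",         "",                                   FALSE),
    list("eating_home",        "Eating at home",                   "daily_living",       "low",    "none", "home",         "",                                   FALSE),
    list("housework",          "Housework",                        "daily_living",       "low",    "none", "home",         "",                                   FALSE),
    list("relaxing_home",      "Relaxing at home",                 "daily_living",       "low",    "none", "home",         "",                                   FALSE),
    list("phone_socializing",  "Talking on the phone",             "daily_living",       "low",    "none", "home",         "",                                   FALSE),
    list("work_main",          "Working, main job",                "daily_living",       "low",    "none", "work",         "",                                   FALSE),
    list("work_social",        "Socializing as part of job",       "daily_living",       "high",   "none", "work",         "",                                   FALSE),
    list("school_attend",      "Attending class",                  "daily_living",       "low",    "none", "school",       "",                                   FALSE),
    list("grocery_shopping",   "Grocery shopping",                 "daily_living",       "medium", "none", "out_of_home",  "",                                   FALSE),
    list("errands",            "Errands and shopping",             "daily_living",       "medium", "none", "out_of_home",  "",                                   FALSE),
    list("socializing_out",    "Socializing away from home",       "daily_living",       "medium", "none", "out_of_home",  "",                                   FALSE),
    list("eating_out",         "Eating out",                       "daily_living",       "medium", "none", "out_of_home",  "",                                   FALSE),
    list("helping_hh_adults",  "Helping household adults",         "daily_living",       "medium", "none", "home",         "",                                   FALSE),
    list("fitness",            "Exercise and fitness",             "health_maintenance", "medium", "AB",   "service_site", "fitness;group_exercise;walking_group", FALSE),
    list("spiritual_practice", "Spiritual practice",               "health_maintenance", "medium", "AB",   "service_site", "spiritual_services",                 FALSE),
    list("weight_mgmt_class",  "Weight management class",          "health_maintenance", "medium", "AB",   "service_site", "weight_management",                  FALSE),
    list("self_care_health",   "Health-related self-care",         "health_maintenance", "medium", "AB",   "service_site", "mental_health;smoking_cessation",    FALSE),
    list("produce_shopping",   "Getting fresh fruits and vegetables", "health_maintenance", "medium", "AB", "service_site", "fresh_produce;food_pantry",          FALSE),
    list("medical_care_self",  "Obtaining medical care",           "health_maintenance", "high",   "none", "service_site", "primary_care",                       TRUE),
    list("medical_care_hh",    "Obtaining medical and care services for household adult", "health_maintenance", "high", "none", "service_site", "primary_care", TRUE)
  ))
  setnames(dt, c("code", "label", "activity_class", "p_level", "decision_type",
                 "location_policy", "mapped_services", "clinic_trigger"))
  dt[, activity_id := seq_len(.N)]
  setcolorder(dt, "activity_id")
  validate_activity_catalog(dt)
  dt[]
}

#' Read an activity catalog from CSV
#' @param path CSV with the columns of [default_activity_catalog()]
#'   (`activity_id` optional; `clinic_trigger` logical)
#' @return validated catalog data.table
#' @export
read_activity_catalog <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "mapped_services"))
  if (!"activity_id" %in% names(dt)) dt[, activity_id := seq_len(.N)]
  if (!"clinic_trigger" %in% names(dt)) dt[, clinic_trigger := FALSE]
  dt[is.na(mapped_services), mapped_services := ""]
  setcolorder(dt, c("activity_id", "code"))
  validate_activity_catalog(dt)
  dt[]
}

validate_activity_catalog <- function(dt) {
  stopifnot(all(dt$p_level %in% c("none", "low", "medium", "high")))
  stopifnot(all(dt$decision_type %in% c("AB", "none")))
  stopifnot(all(dt$location_policy %in%
                  c("home", "work", "school", "out_of_home", "service_site")))
  ab <- dt$decision_type == "AB"
  if (any(ab & !nzchar(dt$mapped_services)))
    abort_config("AB-decision activities must map to at least one service")
  if (anyDuplicated(dt$code)) abort_config("duplicate activity codes")
  invisible(TRUE)
}

#' Schedule-pool configuration
#'
#' @param templates_per_stratum integer range; the number of templates per
#'   (age band, sex, race, ethnicity, day type) stratum is drawn uniformly
#'   from it (minimum 2)
#' @param health_maintenance_freq probability that a template contains an
#'   A/B health-maintenance activity hour (a second one is added with the
#'   squared probability)
#' @param clinic_visit_rate_weekday,clinic_visit_rate_weekend probability
#'   that a template contains a medical-care (clinic visit) hour; because
#'   agents redraw a template every simulated day, this is also the expected
#'   per-agent daily clinic-visit rate
#' @param p_rates named receipt-propensity rates for levels
#'   `none`/`low`/`medium`/`high`; must be non-decreasing with `none` = 0
#' @param work_social_freq probability a weekday work template contains a
#'   work-socializing hour
#' @param school_freq probability a 16-30 weekday template is a school day
#' @return `crx_schedule_config` list
#' @export
schedule_config <- function(templates_per_stratum = c(20L, 80L),
                            health_maintenance_freq = 0.25,
                            clinic_visit_rate_weekday = 0.01,
                            clinic_visit_rate_weekend = 0.005,
                            p_rates = c(none = 0, low = 0.05,
                                        medium = 0.15, high = 0.30),
                            work_social_freq = 0.3,
                            school_freq = 0.3) {
  if (templates_per_stratum[1] < 2L)
    abort_config("each stratum needs at least 2 templates")
  stopifnot(length(p_rates) == 4,
            all(names(p_rates) == c("none", "low", "medium", "high")))
  if (p_rates[["none"]] != 0) abort_config("p_rates['none'] must be 0")
  if (is.unsorted(p_rates) || any(p_rates < 0) || any(p_rates > 1))
    abort_config("p_rates must satisfy 0 = none <= low <= medium <= high <= 1")
  structure(list(templates_per_stratum = as.integer(templates_per_stratum),
                 health_maintenance_freq = health_maintenance_freq,
                 clinic_visit_rate_weekday = clinic_visit_rate_weekday,
                 clinic_visit_rate_weekend = clinic_visit_rate_weekend,
                 p_rates = p_rates,
                 work_social_freq = work_social_freq,
                 school_freq = school_freq),
            class = "crx_schedule_config")
}

stratum_key <- function(band, sex, race, ethnicity, day_type) {
  paste(band, sex, race, ethnicity, day_type, sep = "|")
}

#' Build a synthetic schedule pool
#'
#' Generates, for every demographic stratum (age band x sex x race x
#' ethnicity) and day type, a pool of 24-hour activity templates. Every
#' template sleeps at least 6 hours (hours 0-5 plus hour 23); weekday
#' templates for working-age strata hold a 9-hour work (or school) block;
#' evening and daytime leisure hours are random draws from the daily-living
#' activities; health-maintenance A/B activities and clinic-visit hours are
#' inserted at the configured frequencies. Deterministic for a fixed seed.
#'
#' @param config a [schedule_config()]
#' @param demographics a [demographic_config()] supplying the demographic
#'   label sets the strata are built over
#' @param catalog an activity catalog (default [default_activity_catalog()])
#' @param seed integer RNG seed
#' @return a `crx_pool` with the catalog, template metadata, an integer
#'   hours matrix (templates x 24 activity ids), `p_rates` and a stratum
#'   index
#' @export
build_synthetic_pool <- function(config = schedule_config(),
                                 demographics = demographic_config(),
                                 catalog = default_activity_catalog(),
                                 seed = 1L) {
  stopifnot(inherits(config, "crx_schedule_config"))
  set.seed(seed)
  id_of <- function(code) {
    i <- match(code, catalog$code)
    if (anyNA(i)) abort_config("activity '%s' missing from catalog",
                               code[which(is.na(i))[1]])
    catalog$activity_id[i]
  }
  ev_pool <- id_of(c("eating_home", "relaxing_home", "socializing_out",
                     "eating_out", "helping_hh_adults", "phone_socializing"))
  day_pool <- id_of(c("housework", "relaxing_home", "phone_socializing",
                      "errands", "grocery_shopping", "socializing_out"))
  ab_pool <- catalog[decision_type == "AB", activity_id]
  clinic_pool <- catalog[clinic_trigger == TRUE, activity_id]

  strata <- data.table::CJ(age_band = age_band_labels,
                           sex = names(demographics$sex_proportions),
                           race = names(demographics$race_proportions),
                           ethnicity = names(demographics$ethnicity_proportions),
                           day_type = c("weekday", "weekend"))
  rows <- vector("list", nrow(strata))
  meta <- vector("list", nrow(strata))
  for (s in seq_len(nrow(strata))) {
    st <- strata[s]
    n_t <- config$templates_per_stratum[1] +
      sample.int(diff(config$templates_per_stratum) + 1L, 1L) - 1L
    working <- st$age_band %in% c("16-30", "31-45", "46-65")
    weekday <- st$day_type == "weekday"
    clinic_rate <- if (weekday) config$clinic_visit_rate_weekday
                   else config$clinic_visit_rate_weekend
    m <- matrix(0L, nrow = n_t, ncol = 24L)
    for (j in seq_len(n_t)) {
      h <- integer(24)
      h[1:6] <- id_of("sleeping")          # hours 0-5
      h[7] <- id_of("grooming")
      h[8] <- id_of("eating_home")
      if (weekday && working) {
        block <- if (st$age_band == "16-30" && runif(1) < config$school_freq)
          id_of("school_attend") else id_of("work_main")
        h[9:17] <- block                   # hours 8-16
        if (block == id_of("work_main") && runif(1) < config$work_social_freq)
          h[8 + sample.int(9L, 1L)] <- id_of("work_social")
        h[18] <- resample(day_pool, 1L)    # hour 17
      } else {
        h[9:18] <- resample_with_replacement(day_pool, 10L)
      }
      h[19:22] <- resample_with_replacement(ev_pool, 4L)   # hours 18-21
      h[23] <- resample(c(id_of("relaxing_home"), id_of("sleeping")), 1L)
      h[24] <- id_of("sleeping")
      ## health-maintenance insertions into leisure hours
      leisure <- which(!(h %in% id_of(c("sleeping", "grooming", "work_main",
                                        "work_social", "school_attend"))))
      leisure <- leisure[leisure >= 9 & leisure <= 22]
      if (length(leisure) && runif(1) < config$health_maintenance_freq) {
        slot <- resample(leisure, 1L)
        h[slot] <- resample(ab_pool, 1L)
        leisure <- setdiff(leisure, slot)
        if (length(leisure) && runif(1) < config$health_maintenance_freq^2)
          h[resample(leisure, 1L)] <- resample(ab_pool, 1L)
      }
      if (length(leisure) && length(clinic_pool) && runif(1) < clinic_rate)
        h[resample(leisure, 1L)] <- resample(clinic_pool, 1L)
      m[j, ] <- h
    }
    rows[[s]] <- m
    meta[[s]] <- st[rep(1L, n_t)]
  }
  hours <- do.call(rbind, rows)
  templates <- data.table::rbindlist(meta)
  templates[, template_id := seq_len(.N)]
  setcolorder(templates, "template_id")
  idx <- split(templates$template_id,
               stratum_key(templates$age_band, templates$sex, templates$race,
                           templates$ethnicity, templates$day_type))
  pool <- structure(list(catalog = catalog, templates = templates,
                         hours = hours, p_rates = config$p_rates,
                         index = idx, config = config, seed = as.integer(seed)),
                    class = "crx_pool")
  bad <- vapply(idx, length, 1L) < 2L
  if (any(bad))
    abort_config("stratum %s has fewer than 2 templates", names(idx)[bad][1])
  pool
}

resample_with_replacement <- function(x, k) x[sample.int(length(x), k, replace = TRUE)]

#' @export
print.crx_pool <- function(x, ...) {
  cat(sprintf("<crx_pool> %d templates over %d strata, %d activities\n",
              nrow(x$templates), length(x$index), nrow(x$catalog)))
  invisible(x)
}

#' Template ids matched to a demographic stratum
#'
#' Exact match on (age band, sex, race, ethnicity, day type); if the pool
#' has no templates for the full key, ethnicity is dropped, then race.
#' @param pool a `crx_pool`
#' @param band,sex,race,ethnicity demographic labels
#' @param day_type `"weekday"` or `"weekend"`
#' @return integer template ids (rows of `pool$hours`)
#' @export
match_templates <- function(pool, band, sex, race, ethnicity, day_type) {
  k <- stratum_key(band, sex, race, ethnicity, day_type)
  ids <- pool$index[[k]]
  if (!is.null(ids)) return(ids)
  ## fallback: drop ethnicity, then race
  tm <- pool$templates
  sel <- tm$age_band == band & tm$sex == sex & tm$race == race &
    tm$day_type == day_type
  if (any(sel)) return(tm$template_id[sel])
  sel <- tm$age_band == band & tm$sex == sex & tm$day_type == day_type
  if (any(sel)) return(tm$template_id[sel])
  abort_config("no schedule templates for stratum %s (even after fallback)", k)
}

#' Draw a daily schedule for an agent
#'
#' A fresh uniform draw over the agent's matched templates, to be repeated
#' every simulated day.
#' @param agent one-row agent table (needs `age`, `sex`, `race`, `ethnicity`)
#' @param day_type `"weekday"` or `"weekend"`
#' @param pool a `crx_pool`
#' @return list with `template_id` and the 24-vector `hours` of activity ids
#' @export
draw_daily_schedule <- function(agent, day_type, pool) {
  ids <- match_templates(pool, as.character(age_band(agent$age)), agent$sex,
                         agent$race, agent$ethnicity, day_type)
  id <- ids[sample.int(length(ids), 1L)]
  list(template_id = id, hours = pool$hours[id, ])
}

#' Information-receipt propensity of an activity
#'
#' A pure lookup of the pool's rate for the activity's ordinal propensity
#' level; `none` is always 0.
#' @param activity one-row catalog entry or an activity code
#' @param pool a `crx_pool`
#' @return probability in \[0, 1\]
#' @export
p_score <- function(activity, pool) {
  if (is.character(activity))
    activity <- pool$catalog[pool$catalog$code == activity]
  if (nrow(activity) != 1L) abort_config("unknown activity")
  unname(pool$p_rates[[activity$p_level]])
}

#' Mean weekly minutes of service exposure by age group
#'
#' For each service type, the average number of minutes per week an agent
#' spends doing activities mapped to that service, averaged over the
#' agent's matched templates (5 weekday draws + 2 weekend draws per week)
#' and then within four reporting age groups (<31, 31-45, 46-65, 65+).
#'
#' @param pool a `crx_pool`
#' @param agents agent table (needs `age`, `sex`, `race`, `ethnicity`)
#' @return data.table `service_type` x `age_group` -> `mean_minutes_week`
#' @export
service_exposure_minutes <- function(pool, agents) {
  if (nrow(agents) == 0L) abort_config("empty agent table")
  cat <- pool$catalog
  n_act <- nrow(cat)
  ## minutes per template per activity
  counts <- t(apply(pool$hours, 1L, tabulate, nbins = n_act)) * 60
  ## per-agent expected weekly minutes per activity, via stratum means
  agents <- as.data.table(agents)
  agents[, `:=`(.band = as.character(age_band(age)))]
  stratum_mean <- function(day_type) {
    keys <- unique(agents[, .(.band, sex, race, ethnicity)])
    mats <- lapply(seq_len(nrow(keys)), function(i) {
      ids <- match_templates(pool, keys$.band[i], keys$sex[i], keys$race[i],
                             keys$ethnicity[i], day_type)
      colMeans(counts[ids, , drop = FALSE])
    })
    keys[, row := .I]
    list(keys = keys, mat = do.call(rbind, mats))
  }
  wd <- stratum_mean("weekday")
  we <- stratum_mean("weekend")
  irow <- wd$keys[agents, on = c(".band", "sex", "race", "ethnicity"), row]
  weekly <- 5 * wd$mat[irow, , drop = FALSE] + 2 * we$mat[irow, , drop = FALSE]
  grp <- age_group(agents$age)
  ## expand activity -> services
  svc_map <- lapply(strsplit(cat$mapped_services, ";", fixed = TRUE),
                    function(s) s[nzchar(s)])
  all_svc <- sort(unique(unlist(svc_map)))
  out <- data.table::CJ(service_type = all_svc, age_group = levels(grp))
  out[, mean_minutes_week := 0]
  for (g in levels(grp)) {
    sel <- grp == g
    if (!any(sel)) next
    act_mean <- colMeans(weekly[sel, , drop = FALSE])
    for (a in seq_len(n_act)) {
      for (s in svc_map[[a]]) {
        out[service_type == s & age_group == g,
            mean_minutes_week := mean_minutes_week + act_mean[a]]
      }
    }
  }
  out[]
}

#' Write pool tables to CSV (activities.csv, schedules.csv)
#' @param pool a `crx_pool`
#' @param dir output directory (created if needed)
#' @return invisibly, the file paths
#' @export
write_pool <- function(pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "activities.csv")
  fs <- file.path(dir, "schedules.csv")
  data.table::fwrite(pool$catalog, fa)
  sched <- cbind(pool$templates,
                 as.data.table(pool$hours)[, setNames(.SD, sprintf("h%02d", 0:23))])
  data.table::fwrite(sched, fs)
  invisible(c(fa, fs))
}
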