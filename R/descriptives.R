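#' Crude mortality rate with Poisson confidence interval
#'
#' Events per `scale` person-years, with a 95% CI on the log scale,
#' `rate * exp(±1.96 / sqrt(deaths))`. With zero deaths the rate is 0 and
#' the upper bound is the exact Poisson bound `scale * 3.69 / person_years`
#' (3.69 = upper 97.5% limit of a Poisson mean given 0 observed).
#'
#' @param deaths number of deaths (vectorised).
#' @param person_years follow-up time in years.
#' @param scale rate denominator, 100 (mortality convention) or 1000.
#' @return tibble: `events`, `person_years`, `rate`, `ci_low`, `ci_high`,
#'   `scale`.
#' @export
#' @examples
#' mortality_rate(16890, 107789)  # 15.7 per 100 person-years
mortality_rate <- function(deaths, person_years, scale = 100) {
  if (any(person_years <= 0)) abort("person_years must be positive")
  if (any(deaths < 0)) abort("deaths must be non-negative")
  rate <- scale * deaths / person_years
  ci_low <- ifelse(deaths == 0, 0, rate * exp(-1.96 / sqrt(deaths)))
  ci_high <- ifelse(deaths == 0, scale * 3.69 / person_years,
                    rate * exp(1.96 / sqrt(deaths)))
  tibble(events = deaths, person_years = person_years, rate = rate,
         ci_low = ci_low, ci_high = ci_high, scale = scale)
}

#' Crude fracture incidence rate
#'
#' [mortality_rate()] at the fracture-incidence convention of events per
#' 1000 person-years.
#'
#' @param fractures number of incident fractures.
#' @inheritParams mortality_rate
#' @export
incidence_rate <- function(fractures, person_years, scale = 1000) {
  mortality_rate(fractures, person_years, scale = scale)
}

#' Cohort summary tables
#'
#' Registry-style descriptives: a baseline table (counts, mean (SD) entry
#' age, Charlson distribution, condition prevalences, stratified by sex,
#' fracture and vital status) and a mortality table (per-site post-fracture
#' deaths, person-years and crude rates per 100 person-years; the
#' no-fracture row counts never-fractured persons with their full
#' follow-up).
#'
#' @param persons eligible person tibble.
#' @param fractures index-fracture tibble (one row per fractured person).
#' @param records counting-process tibble from [build_counting_process()].
#' @return list with tibbles `baseline` and `mortality`.
#' @export
cohort_summary <- function(persons, fractures, records) {
  fractured_ids <- unique(fractures$person_id)
  p <- persons |>
    mutate(
      fractured = .data$person_id %in% fractured_ids,
      dead = !is.na(.data$death_date),
      entry_age = as.numeric(.data$entry_date - .data$birth_date) /
        DAYS_PER_YEAR,
      charlson = charlson_index_str(.data$baseline_conditions)
    )

  baseline <- p |>
    group_by(.data$sex, .data$fractured, .data$dead) |>
    summarise(
      n = n(),
      age_mean = mean(.data$entry_age),
      age_sd = sd(.data$entry_age),
      charlson_median = median(.data$charlson),
      charlson_q1 = unname(quantile(.data$charlson, 0.25)),
      charlson_q3 = unname(quantile(.data$charlson, 0.75)),
      .groups = "drop"
    )

  # mortality strata: never-fractured full follow-up vs post-fracture time
  nonfr <- records |>
    filter(!.data$person_id %in% fractured_ids) |>
    group_by(.data$sex) |>
    summarise(site = "no_fracture", n = dplyr::n_distinct(.data$person_id),
              deaths = sum(.data$event),
              person_years = sum(.data$stop - .data$start),
              .groups = "drop")
  post <- filter(records, .data$exposed == 1L)
  by_site <- post |>
    group_by(.data$sex, .data$site) |>
    summarise(n = n(), deaths = sum(.data$event),
              person_years = sum(.data$stop - .data$start),
              .groups = "drop")
  any_frac <- post |>
    group_by(.data$sex) |>
    summarise(site = "any_fracture", n = n(), deaths = sum(.data$event),
              person_years = sum(.data$stop - .data$start),
              .groups = "drop")
  mortality <- bind_rows(nonfr, any_frac, by_site) |>
    mutate(mortality_rate(.data$deaths, .data$person_years, scale = 100) |>
             select("rate", "ci_low", "ci_high")) |>
    arrange(.data$sex, .data$site != "no_fracture",
            .data$site != "any_fracture", .data$site)

  list(baseline = baseline, mortality = mortality)
}
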