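#' Apply the cohort eligibility and fracture-analyzability rules
#'
#' Removes persons with a 1996-2000 (washout) fracture history, drops
#' high-trauma events and events at never-analyzable sites (face, skull,
#' finger, toe), and restricts the remaining events to the fracture
#' ascertainment window.
#'
#' @param persons person tibble as produced by [simulate_cohort()].
#' @param fractures fracture-event tibble.
#' @param hierarchy site table from [site_hierarchy()].
#' @param fracture_window_end last calendar date of fracture ascertainment.
#' @return list with `persons` (eligible) and `fractures` (analyzable).
#' @export
apply_exclusions <- function(persons, fractures,
                             hierarchy = site_hierarchy(),
                             fracture_window_end = as.Date("2014-12-31")) {
  unknown <- setdiff(fractures$site, hierarchy$site)
  if (length(unknown) > 0) {
    abort(paste0("unknown fracture site label(s): ",
                 paste(unique(unknown), collapse = ", ")))
  }
  eligible <- filter(persons, !.data$prior_fracture_1996_2000)
  keep_sites <- hierarchy$site[hierarchy$analyzable]
  analyzable <- fractures |>
    filter(.data$person_id %in% eligible$person_id,
           .data$trauma == "low",
           .data$site %in% keep_sites,
           .data$event_date <= fracture_window_end) |>
    left_join(select(eligible, "person_id", "entry_date"),
              by = "person_id") |>
    filter(.data$event_date >= .data$entry_date) |>
    select(-"entry_date")
  list(persons = eligible, fractures = analyzable)
}

#' Select the index fracture
#'
#' The first incident analyzable fracture defines the exposure. The earliest
#' event date wins; among events on the same day (one clinical event coded at
#' several sites) the most proximal site wins.
#'
#' @param fractures analyzable fracture events, possibly several per person.
#' @param hierarchy site table from [site_hierarchy()].
#' @return tibble with one row per person: the index fracture.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   person_id = "A",
#'   event_date = as.Date(c("2005-03-01", "2005-03-01")),
#'   site = c("forearm", "hip"), trauma = "low",
#'   conditions_at_fracture = ""
#' )
#' select_index_fracture(ev)$site  # "hip"
select_index_fracture <- function(fractures, hierarchy = site_hierarchy()) {
  if (nrow(fractures) == 0) return(fractures)
  fractures |>
    mutate(.rank = hierarchy$rank[match(.data$site, hierarchy$site)]) |>
    group_by(.data$person_id) |>
    arrange(.data$event_date, .data$.rank, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select(-".rank")
}

#' Build the counting-process dataset
#'
#' Converts persons and their index fractures into start/stop records on the
#' years-since-entry clock. A person without a fracture contributes a single
#' unexposed record from entry to death or administrative censoring, with
#' baseline covariates. A fractured person contributes two contiguous
#' records split at the fracture date: the pre-fracture (unexposed) record
#' carries the covariates at study entry and the post-fracture (exposed)
#' record carries the age and Charlson score at the time of fracture. This
#' pre/post splitting is what protects the downstream Cox model from
#' immortal time bias. If death is recorded on the fracture date itself the
#' exposed interval is kept with a one-day minimum length.
#'
#' @param persons eligible person tibble.
#' @param index_fractures one index fracture per person (see
#'   [select_index_fracture()]).
#' @param weights Charlson weight table.
#' @param study_end administrative censoring date.
#' @return tibble of counting-process records with columns `person_id`,
#'   `cluster_id`, `start`, `stop`, `event`, `exposed`, `site`,
#'   `age_covariate`, `charlson_index`, `charlson_category`, `sex`.
#' @export
build_counting_process <- function(persons, index_fractures,
                                   weights = charlson_weights(),
                                   study_end = as.Date("2016-12-31")) {
  if (nrow(index_fractures) > 0 &&
      anyDuplicated(index_fractures$person_id) > 0) {
    abort("index_fractures must contain at most one row per person")
  }
  p <- persons |>
    mutate(
      entry_age = as.numeric(.data$entry_date - .data$birth_date) /
        DAYS_PER_YEAR,
      exit_years = dplyr::if_else(
        is.na(.data$death_date),
        as.numeric(study_end + 1 - .data$entry_date) / DAYS_PER_YEAR,
        as.numeric(.data$death_date - .data$entry_date) / DAYS_PER_YEAR),
      event = as.integer(!is.na(.data$death_date)),
      charlson_index = charlson_index_str(.data$baseline_conditions, weights),
      charlson_category = as.character(
        charlson_category(.data$charlson_index))
    )
  if (any(!is.na(p$death_date) & p$death_date > study_end)) {
    abort("death_date after study_end: data integrity violation")
  }

  fr <- index_fractures |>
    left_join(select(p, "person_id", "entry_date", "death_date",
                     "exit_years", "entry_age"),
              by = "person_id")
  if (nrow(fr) > 0) {
    if (any(is.na(fr$entry_date))) {
      abort("index fracture for a person absent from the person table")
    }
    bad <- !is.na(fr$death_date) & fr$event_date > fr$death_date
    if (any(bad)) abort("fracture after death: data integrity violation")
    if (any(fr$event_date > study_end)) {
      abort("fracture after study_end: data integrity violation")
    }
    fr <- fr |>
      mutate(
        tf = as.numeric(.data$event_date - .data$entry_date) / DAYS_PER_YEAR,
        charlson_index_frac = charlson_index_str(
          .data$conditions_at_fracture, weights),
        # one-day minimum so a same-day death never yields a zero interval
        stop_exposed = pmax(.data$exit_years, .data$tf + 1 / DAYS_PER_YEAR)
      )
  }

  fractured_ids <- fr$person_id
  nonfr <- filter(p, !.data$person_id %in% fractured_ids)

  rec_nonfr <- tibble(
    person_id = nonfr$person_id,
    cluster_id = nonfr$person_id,
    start = 0,
    stop = nonfr$exit_years,
    event = nonfr$event,
    exposed = 0L,
    site = NA_character_,
    age_covariate = nonfr$entry_age,
    charlson_index = nonfr$charlson_index,
    charlson_category = nonfr$charlson_category,
    sex = nonfr$sex
  )

  if (nrow(fr) > 0) {
    pf <- p[match(fr$person_id, p$person_id), ]
    rec_pre <- tibble(
      person_id = fr$person_id,
      cluster_id = fr$person_id,
      start = 0,
      stop = fr$tf,
      event = 0L,
      exposed = 0L,
      site = NA_character_,
      age_covariate = fr$entry_age,
      charlson_index = pf$charlson_index,
      charlson_category = pf$charlson_category,
      sex = pf$sex
    )
    rec_post <- tibble(
      person_id = fr$person_id,
      cluster_id = fr$person_id,
      start = fr$tf,
      stop = fr$stop_exposed,
      event = pf$event,
      exposed = 1L,
      site = fr$site,
      age_covariate = fr$entry_age + fr$tf,
      charlson_index = fr$charlson_index_frac,
      charlson_category = as.character(
        charlson_category(fr$charlson_index_frac)),
      sex = pf$sex
    )
    # a fracture on the entry date has no pre-fracture person-time
    rec_pre <- filter(rec_pre, .data$stop > .data$start)
    out <- bind_rows(rec_nonfr, rec_pre, rec_post)
  } else {
    out <- rec_nonfr
  }
  arrange(out, .data$person_id, .data$start)
}
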