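#' Default site-specific fracture incidence (per 1000 person-years)
#'
#' Per-site first-fracture rates for the registry simulator. Analyzable-site
#' rates are the registry's site shares of all incident fractures scaled so
#' that the low-trauma analyzable first-fracture process runs at 10.9/1000
#' person-years in men and 23.2/1000 in women (the division by
#' `1 - trauma_high_fraction` compensates for high-trauma thinning). The
#' never-analyzable sites (face, skull, finger, toe) get small nominal rates
#' so the exclusion rules are exercised.
#'
#' @param trauma_high_fraction probability that any simulated fracture is
#'   high-trauma (and hence excluded from analysis).
#' @return tibble with columns `site`, `rate_men`, `rate_women` (per 1000
#'   person-years).
#' @export
default_site_incidence <- function(trauma_high_fraction = 0.05) {
  counts <- tibble(
    site = c("hip", "femur", "pelvis", "vertebrae", "humerus", "rib",
             "clavicle", "lower_leg", "forearm", "knee", "ankle", "hand",
             "foot"),
    men = c(25706, 1910, 1305, 6924, 10126, 6867, 5201, 6296, 15268,
            1382, 1084, 8309, 4994),
    women = c(51669, 3529, 4920, 9732, 28298, 3153, 4480, 11460, 68333,
              2604, 1936, 12489, 9916)
  )
  tot <- c(men = 10.9, women = 23.2) / (1 - trauma_high_fraction)
  main <- tibble(
    site = counts$site,
    rate_men = counts$men / sum(counts$men) * tot[["men"]],
    rate_women = counts$women / sum(counts$women) * tot[["women"]]
  )
  extra <- tibble(
    site = c("face", "skull", "finger", "toe"),
    rate_men = c(0.3, 0.2, 0.8, 0.5),
    rate_women = c(0.3, 0.15, 0.7, 0.6)
  )
  bind_rows(main, extra)
}

#' Default true post-fracture mortality hazard ratios
#'
#' The multiplicative excess mortality applied after the index fracture in
#' the simulator, one value per analyzable site (same in both sexes).
#' Ordering follows the field's consistent finding: hip and femur roughly
#' double mortality, other proximal sites carry intermediate excess, and the
#' most distal sites carry little or none.
#'
#' @return tibble with columns `site` and `hr`.
#' @export
default_site_hr <- function() {
  tibble(
    site = c("hip", "femur", "pelvis", "vertebrae", "humerus", "rib",
             "clavicle", "lower_leg", "forearm", "knee", "ankle", "hand",
             "foot"),
    hr = c(2.0, 1.9, 1.7, 1.6, 1.5, 1.35, 1.3, 1.2, 1.05, 1.05, 1.05,
           1.0, 1.0)
  )
}

#' Default comorbidity prevalence model
#'
#' Independent Bernoulli conditions with a logistic age gradient: prevalence
#' is specified at the reference age of 65 and the odds are multiplied by
#' `or_per_decade` for every decade of age above 65.
#'
#' @return tibble with columns `condition`, `prev_men`, `prev_women`,
#'   `or_per_decade`.
#' @export
default_comorbidity_model <- function() {
  tibble(
    condition = c(
      "myocardial_infarction", "congestive_heart_failure", "stroke",
      "peripheral_vascular_disease", "arrhythmias", "hypertension",
      "diabetes", "diabetes_with_complications", "renal_disease", "cancer",
      "metastatic_tumors", "dementia", "chronic_lung_disease",
      "rheumatologic_disease", "mild_liver_disease",
      "moderate_severe_liver_disease", "hemiplegia", "hiv_aids"
    ),
    prev_men = c(0.050, 0.045, 0.065, 0.038, 0.040, 0.048, 0.060, 0.020,
                 0.016, 0.095, 0.012, 0.016, 0.058, 0.015, 0.010, 0.003,
                 0.003, 0.0004),
    prev_women = c(0.022, 0.032, 0.055, 0.024, 0.034, 0.046, 0.044, 0.012,
                   0.009, 0.095, 0.012, 0.020, 0.058, 0.030, 0.008, 0.002,
                   0.002, 0.0001),
    or_per_decade = c(1.9, 2.1, 2.0, 1.9, 2.0, 1.5, 1.6, 1.7, 1.8, 1.8,
                      1.6, 3.0, 1.7, 1.3, 1.1, 1.1, 1.4, 0.8)
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the registry simulator. Defaults describe a cohort
#' entering on 2001-01-01 aged 50+, followed for incident low-trauma
#' fracture to end-2014 and mortality to end-2016, with Gompertz background
#' mortality (B = 3.47e-5 men / 1.89e-5 women, slope k = 0.095/year) and
#' multiplicative post-fracture excess mortality.
#'
#' @param n_persons number of persons to simulate.
#' @param seed integer RNG seed (mandatory).
#' @param entry_date,fracture_window_end,study_end calendar dates.
#' @param sex_ratio fraction male.
#' @param entry_age_mean_men,entry_age_sd_men,entry_age_mean_women,entry_age_sd_women
#'   normal entry-age parameters (years), truncated below at 50.
#' @param gompertz_B_men,gompertz_B_women baseline hazard scale per year.
#' @param gompertz_k log-hazard slope per year of age.
#' @param site_incidence tibble `site, rate_men, rate_women` (per 1000 PY).
#' @param site_hr tibble `site, hr` of true post-fracture hazard ratios.
#' @param comorbidity_model tibble from [default_comorbidity_model()].
#' @param comorbidity_mortality_hr named numeric, mortality multiplier per
#'   Charlson category `c("0", "1-2", "3-4", "5+")`.
#' @param washout_fraction fraction of persons flagged with a 1996-2000
#'   fracture history (excluded downstream).
#' @param trauma_high_fraction probability a simulated fracture is
#'   high-trauma.
#' @param condition_accrual_rate per-condition per-year probability of
#'   acquiring an absent condition between entry and fracture (0 keeps the
#'   at-fracture Charlson identical to baseline, the internally consistent
#'   default).
#' @return a `skelage_config` list.
#' @export
sim_config <- function(n_persons,
                       seed,
                       entry_date = as.Date("2001-01-01"),
                       fracture_window_end = as.Date("2014-12-31"),
                       study_end = as.Date("2016-12-31"),
                       sex_ratio = 0.476,
                       entry_age_mean_men = 63.9, entry_age_sd_men = 10.3,
                       entry_age_mean_women = 65.5, entry_age_sd_women = 11.3,
                       gompertz_B_men = 0.0000347,
                       gompertz_B_women = 0.0000189,
                       gompertz_k = 0.095,
                       site_incidence = default_site_incidence(trauma_high_fraction),
                       site_hr = default_site_hr(),
                       comorbidity_model = default_comorbidity_model(),
                       comorbidity_mortality_hr = c("0" = 1, "1-2" = 1.6,
                                                    "3-4" = 2.8, "5+" = 4.5),
                       washout_fraction = 0.08,
                       trauma_high_fraction = 0.05,
                       condition_accrual_rate = 0) {
  cfg <- list(
    n_persons = n_persons, seed = seed,
    entry_date = as.Date(entry_date),
    fracture_window_end = as.Date(fracture_window_end),
    study_end = as.Date(study_end),
    sex_ratio = sex_ratio,
    entry_age_mean_men = entry_age_mean_men,
    entry_age_sd_men = entry_age_sd_men,
    entry_age_mean_women = entry_age_mean_women,
    entry_age_sd_women = entry_age_sd_women,
    gompertz_B_men = gompertz_B_men,
    gompertz_B_women = gompertz_B_women,
    gompertz_k = gompertz_k,
    site_incidence = as_tibble(site_incidence),
    site_hr = as_tibble(site_hr),
    comorbidity_model = as_tibble(comorbidity_model),
    comorbidity_mortality_hr = comorbidity_mortality_hr,
    washout_fraction = washout_fraction,
    trauma_high_fraction = trauma_high_fraction,
    condition_accrual_rate = condition_accrual_rate
  )
  class(cfg) <- "skelage_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_persons) || cfg$n_persons < 1) {
    abort("n_persons must be a positive count")
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) abort("seed is mandatory")
  need <- c("site", "rate_men", "rate_women")
  if (!all(need %in% names(cfg$site_incidence))) {
    abort("site_incidence must have columns site, rate_men, rate_women")
  }
  if (any(cfg$site_incidence$rate_men < 0) ||
      any(cfg$site_incidence$rate_women < 0)) {
    abort("site incidence rates must be non-negative")
  }
  if (!all(c("site", "hr") %in% names(cfg$site_hr)) ||
      any(cfg$site_hr$hr <= 0)) {
    abort("site_hr must have columns site, hr with hr > 0")
  }
  if (any(cfg$comorbidity_mortality_hr <= 0)) {
    abort("comorbidity mortality multipliers must be positive")
  }
  gap <- as.numeric(cfg$study_end - cfg$fracture_window_end) / DAYS_PER_YEAR
  if (gap < 2) {
    abort("study_end must be at least 2 years after fracture_window_end")
  }
  bad <- setdiff(cfg$site_incidence$site, site_hierarchy()$site)
  if (length(bad) > 0) {
    abort(paste0("unknown site(s) in site_incidence: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(cfg)
}

# vectorised ';'-joined condition strings from a logical person x condition
# matrix; most persons carry no condition so only the occupied rows loop
conditions_to_str <- function(cond_mat) {
  out <- rep("", nrow(cond_mat))
  hit <- which(cond_mat, arr.ind = TRUE)
  if (nrow(hit) > 0) {
    labs <- colnames(cond_mat)[hit[, 2]]
    spl <- split(labs, hit[, 1])
    out[as.integer(names(spl))] <-
      vapply(spl, paste, character(1), collapse = ";")
  }
  out
}

# Inverse of the Gompertz cumulative hazard: time to event for hazard
# m * B * exp(k * age), starting at age0, given a unit-exponential draw E.
gompertz_inv <- function(age0, mB, k, E) {
  if (k == 0) return(E / mB)
  log(exp(k * age0) + k * E / mB) / k - age0
}

# truncated-normal (lower bound 50) entry ages via inverse CDF
rtrunc_age <- function(n, mean, sd, lower = 50) {
  u <- runif(n, stats::pnorm(lower, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Simulate a registry cohort
#'
#' Generates a person table and a fracture-event table with the structure the
#' downstream analysis assumes: background mortality follows a Gompertz
#' hazard in chronological age multiplied by a Charlson-category factor,
#' site-specific first fractures arrive as independent exponential clocks,
#' and from the first analyzable low-trauma fracture onwards the mortality
#' hazard is multiplied by the site's true hazard ratio. Follow-up is
#' censored at `study_end`. Only events up to and including the index
#' fracture are emitted (subsequent fractures are out of scope); events at
#' never-analyzable sites and high-trauma events are emitted so the
#' exclusion rules have something to exclude.
#'
#' @param config a [sim_config()] object.
#' @return list with tibbles `persons` (person_id, sex, birth_date,
#'   entry_date, death_date, baseline_conditions, prior_fracture_1996_2000)
#'   and `fractures` (person_id, event_date, site, trauma,
#'   conditions_at_fracture).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_persons = 500, seed = 42))
#' nrow(sim$persons)
simulate_cohort <- function(config) {
  validate_sim_config(config)
  withr::local_seed(config$seed)
  n <- as.integer(config$n_persons)
  k <- config$gompertz_k

  male <- rbinom(n, 1, config$sex_ratio) == 1
  age0 <- ifelse(male,
                 rtrunc_age(n, config$entry_age_mean_men,
                            config$entry_age_sd_men),
                 rtrunc_age(n, config$entry_age_mean_women,
                            config$entry_age_sd_women))
  B <- ifelse(male, config$gompertz_B_men, config$gompertz_B_women)

  # baseline comorbidities: independent Bernoulli with logistic age gradient
  cm_model <- config$comorbidity_model
  cond_mat <- matrix(FALSE, n, nrow(cm_model),
                     dimnames = list(NULL, cm_model$condition))
  for (j in seq_len(nrow(cm_model))) {
    p0 <- ifelse(male, cm_model$prev_men[j], cm_model$prev_women[j])
    odds <- p0 / (1 - p0) * cm_model$or_per_decade[j]^((age0 - 65) / 10)
    cond_mat[, j] <- runif(n) < odds / (1 + odds)
  }
  wt <- charlson_weights()
  w <- wt$weight[match(colnames(cond_mat), wt$condition)]
  charlson0 <- as.integer(cond_mat %*% w)
  cat0 <- as.character(charlson_category(charlson0))
  cm_mult <- unname(config$comorbidity_mortality_hr[cat0])

  prior_frac <- runif(n) < config$washout_fraction

  # pre-fracture death time on the years-since-entry clock
  td0 <- gompertz_inv(age0, cm_mult * B, k, rexp(n))

  # site clocks: first arrival per site, independent exponentials
  sites <- config$site_incidence$site
  rate <- cbind(men = config$site_incidence$rate_men,
                women = config$site_incidence$rate_women) / 1000
  arr <- matrix(Inf, n, length(sites), dimnames = list(NULL, sites))
  for (s in seq_along(sites)) {
    r <- ifelse(male, rate[s, "men"], rate[s, "women"])
    pos <- r > 0
    if (any(pos)) arr[pos, s] <- rexp(sum(pos), r[pos])
  }
  high <- matrix(runif(n * length(sites)) < config$trauma_high_fraction,
                 n, length(sites))
  hier <- site_hierarchy()
  analyzable <- sites %in% hier$site[hier$analyzable]

  window_yr <- as.numeric(config$fracture_window_end + 1 -
                            config$entry_date) / DAYS_PER_YEAR
  censor_yr <- as.numeric(config$study_end + 1 -
                            config$entry_date) / DAYS_PER_YEAR

  # index fracture: earliest low-trauma analyzable arrival
  idx_arr <- arr
  idx_arr[, !analyzable] <- Inf
  idx_arr[high] <- Inf
  tf <- do.call(pmin, as.data.frame(idx_arr))
  site_idx <- sites[max.col(-idx_arr, ties.method = "first")]
  has_index <- is.finite(tf) & tf < pmin(td0, window_yr)

  # post-fracture mortality: hazard multiplied by the site HR from tf on
  td <- td0
  if (any(has_index)) {
    hr <- config$site_hr$hr[match(site_idx[has_index], config$site_hr$site)]
    if (anyNA(hr)) abort("site_hr is missing a site present in site_incidence")
    i <- which(has_index)
    td[i] <- tf[i] + gompertz_inv(age0[i] + tf[i],
                                  cm_mult[i] * hr * B[i], k,
                                  rexp(length(i)))
  }

  died <- td < censor_yr
  entry <- config$entry_date
  max_days <- as.numeric(config$study_end - entry)
  death_date <- dplyr::if_else(died,
                               entry + pmin(ceiling(td * DAYS_PER_YEAR),
                                            max_days),
                               as.Date(NA))

  cond_str <- conditions_to_str(cond_mat)

  persons <- tibble(
    person_id = sprintf("P%06d", seq_len(n)),
    sex = ifelse(male, "male", "female"),
    birth_date = entry - round(age0 * DAYS_PER_YEAR),
    entry_date = entry,
    death_date = death_date,
    baseline_conditions = cond_str,
    prior_fracture_1996_2000 = prior_frac
  )

  # emitted events: the index fracture plus any arrival strictly before it
  # (those are necessarily high-trauma or never-analyzable sites)
  cutoff <- ifelse(has_index, tf, pmin(td0, window_yr))
  ev <- which(arr < matrix(cutoff, n, length(sites)), arr.ind = TRUE)
  fr_list <- list()
  if (nrow(ev) > 0) {
    fr_list$junk <- tibble(
      row = ev[, 1],
      t = arr[ev],
      site = sites[ev[, 2]],
      trauma = ifelse(high[ev], "high", "low")
    )
  }
  if (any(has_index)) {
    i <- which(has_index)
    fr_list$index <- tibble(row = i, t = tf[i], site = site_idx[i],
                            trauma = "low")
  }
  fractures <- if (length(fr_list) > 0) {
    at_frac_conditions <- conditions_at_time(cond_mat, cm_model,
                                             config$condition_accrual_rate)
    fr <- bind_rows(fr_list) |>
      arrange(.data$row, .data$t) |>
      mutate(
        person_id = persons$person_id[.data$row],
        event_date = entry + floor(.data$t * DAYS_PER_YEAR),
        conditions_at_fracture = at_frac_conditions(.data$row, .data$t)
      ) |>
      select("person_id", "event_date", "site", "trauma",
             "conditions_at_fracture")
    fr
  } else {
    tibble(person_id = character(0), event_date = as.Date(character(0)),
           site = character(0), trauma = character(0),
           conditions_at_fracture = character(0))
  }
  list(persons = persons, fractures = fractures)
}

# closure giving the condition string at fracture time; with accrual rate 0
# (the default) this is just the baseline set, keeping the generative
# mortality multiplier and the at-fracture Charlson coding identical
conditions_at_time <- function(cond_mat, cm_model, accrual_rate) {
  base_str <- conditions_to_str(cond_mat)
  function(rows, t) {
    if (accrual_rate <= 0) return(base_str[rows])
    out <- character(length(rows))
    for (i in seq_along(rows)) {
      present <- cond_mat[rows[i], ]
      gain <- runif(length(present)) < (1 - (1 - accrual_rate)^t[i])
      out[i] <- paste(colnames(cond_mat)[present | (gain & !present)],
                      collapse = ";")
    }
    out
  }
}

#' Generate a Gompertz lifetable
#'
#' Tabulates the annual mortality rate `B_sex * exp(k * age)` at integer ages
#' 50-100 for both sexes, standing in for a national lifetable.
#'
#' @param config a [sim_config()] object (only the Gompertz fields are used).
#' @param ages integer ages to tabulate.
#' @return tibble with columns `age`, `sex`, `rate`.
#' @export
generate_lifetable <- function(config, ages = 50:100) {
  validate_sim_config(config)
  tidyr::expand_grid(sex = c("male", "female"), age = as.integer(ages)) |>
    mutate(B = ifelse(.data$sex == "male", config$gompertz_B_men,
                      config$gompertz_B_women),
           rate = .data$B * exp(config$gompertz_k * .data$age)) |>
    select("age", "sex", "rate")
}
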