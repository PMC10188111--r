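# Hand-built 6-person cohort with every structural case: a fractured man who
# dies, a never-fractured death, a survivor, a same-day two-site fracture,
# excluded (finger / high-trauma) events, and a washout exclusion. All
# derived quantities asserted against it were computed by hand from the day
# counts (365.25 days/year).
make_fixture <- function() {
  entry <- as.Date("2001-01-01")
  age_to_birth <- function(a) entry - round(a * 365.25)
  persons <- tibble::tibble(
    person_id = c("M1", "M2", "M3", "F1", "F2", "F3"),
    sex = c("male", "male", "male", "female", "female", "female"),
    birth_date = age_to_birth(c(60, 70, 55, 65, 80, 72)),
    entry_date = entry,
    death_date = as.Date(c("2010-01-01", "2003-01-01", NA, NA,
                           "2012-06-30", NA)),
    baseline_conditions = c("", "metastatic_tumors;renal_disease",
                            "diabetes", "", "stroke", ""),
    prior_fracture_1996_2000 = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  fractures <- tibble::tibble(
    person_id = c("M1", "F1", "F1", "F2", "F2"),
    event_date = as.Date(c("2005-01-01", "2005-03-01", "2005-03-01",
                           "2003-05-10", "2004-02-01")),
    site = c("hip", "forearm", "hip", "finger", "hip"),
    trauma = c("low", "low", "low", "low", "high"),
    conditions_at_fracture = c(
      "myocardial_infarction;congestive_heart_failure", "", "", "", "")
  )
  list(persons = persons, fractures = fractures)
}

# fixture day counts, hand-checked against a calendar
fixture_days <- list(
  m1_fracture = 1461,   # 2001-01-01 -> 2005-01-01 (2004 leap)
  m1_death = 3287,      # 2001-01-01 -> 2010-01-01
  m2_death = 730,       # 2001-01-01 -> 2003-01-01
  f1_fracture = 1520,   # 2001-01-01 -> 2005-03-01
  f2_death = 4198       # 2001-01-01 -> 2012-06-30
)

# simulate -> exclusions -> index -> counting process, in memory
build_sim_records <- function(config) {
  sim <- simulate_cohort(config)
  elig <- apply_exclusions(sim$persons, sim$fractures,
                           fracture_window_end = config$fracture_window_end)
  idx <- select_index_fracture(elig$fractures)
  build_counting_process(elig$persons, idx, study_end = config$study_end)
}

# config with one common true hazard ratio at every analyzable site
uniform_hr_config <- function(n, seed, hr) {
  sh <- default_site_hr()
  sh$hr <- rep(hr, nrow(sh))
  sim_config(n_persons = n, seed = seed, site_hr = sh)
}

# fitted any-fracture estimate from a fresh simulation
sim_any_fracture_fit <- function(n, seed, hr) {
  rec <- build_sim_records(uniform_hr_config(n, seed, hr))
  fit_cox(rec, exposure_coding = "any_fracture")
}

# hand-written estimates table (e.g. to inject known hazard ratios)
estimates_from_hr <- function(site_hr, sex = "male",
                              charlson_betas = c("1-2" = 0.4, "3-4" = 0.9,
                                                 "5+" = 1.4)) {
  exposure <- tibble::tibble(
    sex = sex, term = paste0("exposure", site_hr$site), site = site_hr$site,
    kind = "exposure", beta = log(site_hr$hr), se = 0.05,
    hr = site_hr$hr, ci_low = site_hr$hr * exp(-0.1),
    ci_high = site_hr$hr * exp(0.1)
  )
  covs <- tibble::tibble(
    sex = sex, term = paste0("charlson_category", names(charlson_betas)),
    site = NA_character_, kind = "covariate",
    beta = unname(charlson_betas), se = 0.05,
    hr = exp(unname(charlson_betas)), ci_low = NA_real_, ci_high = NA_real_
  )
  dplyr::bind_rows(exposure, covs)
}

zero_reference_means <- function() {
  stats::setNames(rep(0, 3),
                  paste0("charlson_category", c("1-2", "3-4", "5+")))
}
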