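#' Read/write the pipeline's delimited interchange files
#'
#' All tabular interchange is header-bearing UTF-8 CSV with ISO-8601 dates.
#' `write_estimates()`/`read_estimates()` carry the hazard-ratio contract
#' between the survival model and the skeletal-age stage: exposure and
#' covariate coefficients plus the reference covariate means, so externally
#' supplied (e.g. published) hazard ratios can be injected by hand-writing
#' the same file.
#'
#' @param x object to write.
#' @param path file path.
#' @name skelage-io
NULL

#' @rdname skelage-io
#' @export
write_cohort <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname skelage-io
#' @export
read_persons <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    person_id = "c", sex = "c", birth_date = "D", entry_date = "D",
    death_date = "D", baseline_conditions = "c",
    prior_fracture_1996_2000 = "l")) |>
    mutate(baseline_conditions = dplyr::coalesce(.data$baseline_conditions,
                                                 ""))
}

#' @rdname skelage-io
#' @export
read_fractures <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    person_id = "c", event_date = "D", site = "c", trauma = "c",
    conditions_at_fracture = "c")) |>
    mutate(conditions_at_fracture = dplyr::coalesce(
      .data$conditions_at_fracture, ""))
}

#' @rdname skelage-io
#' @export
read_lifetable <- function(path) {
  readr::read_csv(path, col_types = readr::cols(age = "i", sex = "c",
                                                rate = "d"))
}

#' @rdname skelage-io
#' @export
read_records <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    person_id = "c", cluster_id = "c", start = "d", stop = "d",
    event = "i", exposed = "i", site = "c", age_covariate = "d",
    charlson_index = "i", charlson_category = "c", sex = "c"))
}

#' @rdname skelage-io
#' @param fits list of `skelage_cox` objects whose estimate rows are pooled.
#' @export
write_estimates <- function(fits, path) {
  if (inherits(fits, "skelage_cox")) fits <- list(fits)
  rows <- purrr::map_dfr(fits, function(f) {
    bind_rows(
      f$estimates,
      tibble(sex = f$sex, term = names(f$reference_means),
             site = NA_character_, kind = "reference_mean",
             beta = unname(f$reference_means), se = NA_real_,
             hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    )
  })
  readr::write_csv(rows, path)
  invisible(path)
}

#' @rdname skelage-io
#' @export
read_estimates <- function(path) {
  rows <- readr::read_csv(path, col_types = readr::cols(
    sex = "c", term = "c", site = "c", kind = "c", beta = "d", se = "d",
    hr = "d", ci_low = "d", ci_high = "d"))
  est <- filter(rows, .data$kind != "reference_mean")
  ref <- filter(rows, .data$kind == "reference_mean")
  ref_means <- split(setNames(ref$beta, ref$term), ref$sex)
  list(estimates = est, reference_means = ref_means)
}

#' @rdname skelage-io
#' @export
write_skeletal_age_grid <- function(x, path) {
  # documented output precision: one decimal year
  out <- mutate(as_tibble(x),
                across(c("yll", "skeletal_age", "ci_low", "ci_high"),
                       ~ round(.x, 1)))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname skelage-io
#' @export
read_skeletal_age_grid <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    sex = "c", site = "c", age = "i", yll = "d", skeletal_age = "d",
    ci_low = "d", ci_high = "d"))
  structure(out, class = c("skelage_grid", class(out)))
}

#' Run the full skeletal-age pipeline
#'
#' Orchestrates simulate -> build -> fit -> skeletal-age -> report from one
#' configuration and seed, writing every interchange file plus a JSON run
#' manifest (seed, config hash, stage timings, file digests, package
#' version) to `out_dir`. Identical config and seed give identical output
#' digests. Each stage consumes only the files of its upstream stage, so
#' any stage can be re-run standalone from files.
#'
#' @param config a [sim_config()] object.
#' @param out_dir output directory (created if absent).
#' @param exposure_coding passed to [fit_cox()].
#' @param ages age grid for the skeletal-age table.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir,
                         exposure_coding = "by_site", ages = 50:90) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("skelage")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = list()
  )
  stage <- function(name, f) {
    t0 <- proc.time()[["elapsed"]]
    out <- f()
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    out
  }
  path <- function(f) file.path(out_dir, f)

  sim <- stage("simulate", function() {
    s <- simulate_cohort(config)
    write_cohort(s$persons, path("persons.csv"))
    write_cohort(s$fractures, path("fractures.csv"))
    write_cohort(generate_lifetable(config), path("lifetable.csv"))
    inform(sprintf("simulate: %d persons, %d fracture events",
                   nrow(s$persons), nrow(s$fractures)))
    s
  })

  built <- stage("build", function() {
    persons <- read_persons(path("persons.csv"))
    fractures <- read_fractures(path("fractures.csv"))
    elig <- apply_exclusions(persons, fractures,
                             fracture_window_end = config$fracture_window_end)
    idx <- select_index_fracture(elig$fractures)
    rec <- build_counting_process(elig$persons, idx,
                                  study_end = config$study_end)
    write_cohort(rec, path("records.csv"))
    inform(sprintf("build: %d eligible persons, %d index fractures, %d records",
                   nrow(elig$persons), nrow(idx), nrow(rec)))
    list(eligible = elig, index = idx, records = rec)
  })

  fits <- stage("fit", function() {
    rec <- read_records(path("records.csv"))
    f <- lapply(c("male", "female"), function(sx) {
      fit_cox(rec, sex = sx, exposure_coding = exposure_coding,
              drop_empty_sites = TRUE)
    })
    write_estimates(f, path("estimates.csv"))
    f
  })

  grid <- stage("skeletal_age", function() {
    est <- read_estimates(path("estimates.csv"))
    lt <- read_lifetable(path("lifetable.csv"))
    params <- list(male = fit_gompertz(lt, "male"),
                   female = fit_gompertz(lt, "female"))
    g <- skeletal_age_table(est$estimates, params, lifetable = lt,
                            ages = ages)
    write_skeletal_age_grid(g, path("skeletal_age.csv"))
    g
  })

  stage("report", function() {
    summaries <- cohort_summary(built$eligible$persons, built$index,
                                built$records)
    write_cohort(summaries$baseline, path("summary_baseline.csv"))
    write_cohort(summaries$mortality, path("summary_mortality.csv"))
    checks <- verify_published_rates()
    write_cohort(checks, path("verify_published.csv"))
    NULL
  })

  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest$file_md5 <- as.list(tools::md5sum(files))
  names(manifest$file_md5) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
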