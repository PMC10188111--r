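#' Prognostic index of a risk profile
#'
#' A single-number summary of the combined effect of fracture site and
#' comorbidity severity: the Cox linear predictor over the site indicator
#' and the Charlson-category indicators, centred on the mean linear
#' predictor of 'typical' people (the full cohort at baseline, where nobody
#' is yet fractured so the site contribution of the reference population is
#' zero). Age is deliberately not part of the index: it enters the
#' skeletal-age computation through the evaluation age `z` of the Gompertz
#' hazard instead.
#'
#' @param profile list with elements `sex`, `z` (age), `site`,
#'   `charlson_category` (one of `"0"`, `"1-2"`, `"3-4"`, `"5+"`).
#' @param estimates estimate tibble from [tidy.skelage_cox()] (columns
#'   `term`, `site`, `kind`, `beta`), restricted to one sex.
#' @param reference_means named numeric of baseline covariate means
#'   (`$reference_means` of the fit); names
#'   `charlson_category1-2` etc.
#' @return list with `pi`, `pi_mean`, `delta` (the log-hazard offset of the
#'   profile relative to a typical person).
#' @export
prognostic_index <- function(profile, estimates, reference_means) {
  site_row <- filter(estimates, .data$kind == "exposure",
                     .data$site == profile$site)
  if (nrow(site_row) != 1) {
    abort(paste0("missing exposure coefficient for site: ", profile$site))
  }
  pi_val <- site_row$beta
  pi_mean <- 0
  for (lev in charlson_levels()[-1]) {
    term <- paste0("charlson_category", lev)
    row <- filter(estimates, .data$term == .env$term)
    if (nrow(row) != 1) {
      abort(paste0("missing covariate coefficient: ", term))
    }
    if (identical(profile$charlson_category, lev)) {
      pi_val <- pi_val + row$beta
    }
    if (!term %in% names(reference_means)) {
      abort(paste0("missing reference mean: ", term))
    }
    pi_mean <- pi_mean + row$beta * reference_means[[term]]
  }
  list(pi = pi_val, pi_mean = pi_mean, delta = pi_val - pi_mean)
}

#' Years of life lost for a log-hazard offset
#'
#' Population remaining life expectancy at age `z` (from the lifetable, or
#' from the Gompertz parameters when no lifetable is given) minus the
#' remaining life expectancy under the fracture-elevated hazard
#' `exp(a + delta + b t)`. Under the Gompertz law, multiplying the hazard by
#' `exp(delta)` is exactly equivalent to ageing by `delta / b` years, which
#' is why the result reads as an effective-age increment.
#'
#' @param delta log-hazard offset (e.g. `log(hr)` or a centred prognostic
#'   index difference).
#' @param z chronological age in years.
#' @param params [gompertz_params()] of the population baseline.
#' @param lifetable optional lifetable tibble for the population side.
#' @param sex sex for the lifetable lookup.
#' @return years of life lost (positive when `delta > 0`).
#' @export
yll <- function(delta, z, params, lifetable = NULL, sex = NULL) {
  if (!is.finite(delta)) abort("delta must be finite")
  le_pop <- if (is.null(lifetable)) {
    remaining_le_closed(params, z)
  } else {
    lifetable_le(lifetable, sex, z)
  }
  le_frac <- remaining_le_closed(
    gompertz_params(params$a + delta, params$b), z)
  le_pop - le_frac
}

#' Skeletal age of one risk profile
#'
#' Chronological age plus the years of life lost associated with the
#' profile's fracture, with a 95% confidence interval obtained by replacing
#' the site's log hazard ratio by its confidence limits (baseline-hazard and
#' lifetable uncertainty are ignored, by design).
#'
#' @inheritParams prognostic_index
#' @param estimates estimate tibble (one sex) including `ci_low`/`ci_high`
#'   on the exposure rows.
#' @param params [gompertz_params()] for the profile's sex.
#' @param lifetable optional lifetable for the population side.
#' @return one-row tibble: `sex`, `site`, `z`, `yll`, `skeletal_age`,
#'   `ci_low`, `ci_high`.
#' @export
skeletal_age <- function(profile, estimates, params, lifetable = NULL,
                         reference_means = NULL) {
  if (is.null(reference_means)) {
    reference_means <- setNames(rep(0, 3),
                                paste0("charlson_category",
                                       charlson_levels()[-1]))
  }
  pidx <- prognostic_index(profile, estimates, reference_means)
  site_row <- filter(estimates, .data$kind == "exposure",
                     .data$site == profile$site)
  delta <- pidx$delta
  delta_lo <- delta - site_row$beta + log(site_row$ci_low)
  delta_hi <- delta - site_row$beta + log(site_row$ci_high)
  y <- yll(delta, profile$z, params, lifetable, profile$sex)
  y_lo <- yll(delta_lo, profile$z, params, lifetable, profile$sex)
  y_hi <- yll(delta_hi, profile$z, params, lifetable, profile$sex)
  if (y < 0) {
    warn(sprintf("negative years of life lost (%.2f) for site %s: hr < 1",
                 y, profile$site))
  }
  tibble(
    sex = profile$sex, site = profile$site, z = profile$z,
    yll = y, skeletal_age = profile$z + y,
    ci_low = profile$z + y_lo, ci_high = profile$z + y_hi
  )
}

#' Skeletal-age grid over sites and ages
#'
#' Tabulates years of life lost and skeletal age for every estimated
#' fracture site over a grid of chronological ages, per sex, for a typical
#' comorbidity profile (Charlson contribution at the reference mean, so the
#' log-hazard offset of each site is its log hazard ratio). Confidence
#' limits come from the hazard-ratio confidence limits.
#'
#' @param estimates estimate tibble with a `sex` column covering one or both
#'   sexes (exposure rows with `site`, `beta`, `ci_low`, `ci_high`).
#' @param params a [gompertz_params()] object, or a named list
#'   `list(male = ..., female = ...)`.
#' @param lifetable optional lifetable tibble covering the grid ages.
#' @param ages integer age grid.
#' @return a `skelage_grid` tibble: `sex`, `site`, `age`, `yll`,
#'   `skeletal_age`, `ci_low`, `ci_high`.
#' @export
skeletal_age_table <- function(estimates, params, lifetable = NULL,
                               ages = 50:90) {
  exp_rows <- filter(estimates, .data$kind == "exposure",
                     .data$site != "any", !is.na(.data$site))
  if (nrow(exp_rows) == 0) {
    warn("no site-specific estimates: returning empty table")
    out <- tibble(sex = character(0), site = character(0),
                  age = integer(0), yll = numeric(0),
                  skeletal_age = numeric(0), ci_low = numeric(0),
                  ci_high = numeric(0))
    return(structure(out, class = c("skelage_grid", class(out))))
  }
  get_params <- function(sex) {
    if (inherits(params, "gompertz_params")) params else params[[sex]]
  }
  out <- purrr::map_dfr(unique(exp_rows$sex), function(sx) {
    prm <- get_params(sx)
    # population LE is site-independent: compute once per sex and age
    le_pop <- if (is.null(lifetable)) {
      remaining_le_closed(prm, ages)
    } else {
      lifetable_le(lifetable, sx, ages)
    }
    rows <- filter(exp_rows, .data$sex == sx)
    purrr::map_dfr(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      le_at <- function(d) {
        remaining_le_closed(gompertz_params(prm$a + d, prm$b), ages)
      }
      y <- le_pop - le_at(r$beta)
      tibble(
        sex = sx, site = r$site, age = as.integer(ages),
        yll = y, skeletal_age = ages + y,
        ci_low = ages + (le_pop - le_at(log(r$ci_low))),
        ci_high = ages + (le_pop - le_at(log(r$ci_high)))
      )
    })
  })
  # tolerance excludes quadrature noise around exactly-null sites (hr = 1)
  if (any(out$yll < -1e-9)) {
    warn("negative years of life lost for some sites (hr < 1); reported as computed")
  }
  structure(out, class = c("skelage_grid", class(out)))
}

#' Plot a skeletal-age grid
#'
#' Skeletal age against chronological age, one line per fracture site,
#' facetted by sex; the identity line marks a fracture with no excess
#' mortality.
#'
#' @param object a `skelage_grid` from [skeletal_age_table()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.skelage_grid <- function(object, ...) {
  d <- mutate(as_tibble(object),
              site = factor(.data$site, levels = site_hierarchy()$site))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$skeletal_age,
                                  colour = .data$site)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "Chronological age at fracture (years)",
                  y = "Skeletal age (years)", colour = "Fracture site")
}
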