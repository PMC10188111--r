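#' Fit the time-dependent Cox model
#'
#' Estimates the association between an incident fracture and subsequent
#' mortality from counting-process records, with the fracture entering as a
#' time-dependent exposure (pre/post splitting already done by
#' [build_counting_process()]), adjusted for age and Charlson category,
#' with variance clustered on person and Breslow tie handling.
#'
#' Age is adjusted as age at study entry, recovered exactly as
#' `age_covariate - start`. On the follow-up time scale the common
#' exponential aging of the whole cohort is absorbed by the baseline hazard,
#' so entry age is the person-specific age contribution; carrying the
#' fracture-updated age into the linear predictor instead would double-count
#' follow-up aging differentially for the exposed intervals and bias the
#' exposure coefficient downwards (see the methods vignette).
#'
#' @param records counting-process tibble from [build_counting_process()].
#' @param sex optional: restrict to `"male"` or `"female"` records.
#' @param exposure_coding `"any_fracture"` (single exposure indicator) or
#'   `"by_site"` (one indicator per fracture site).
#' @param drop_empty_sites with `"by_site"` coding, sites whose exposed
#'   records carry no deaths make the model inestimable; the default is an
#'   explicit error, but the pipeline sets `TRUE` to drop those exposed
#'   records (which hold person-time only, no events) with a warning.
#' @return a `skelage_cox` object; see [tidy.skelage_cox()] for the estimate
#'   table (exposure terms with cluster-robust standard errors and 95%
#'   confidence limits) and `$reference_means` for the baseline covariate
#'   means used to centre prognostic indices.
#' @export
fit_cox <- function(records, sex = NULL,
                    exposure_coding = c("any_fracture", "by_site"),
                    drop_empty_sites = FALSE) {
  exposure_coding <- match.arg(exposure_coding)
  d <- records
  if (!is.null(sex)) d <- filter(d, .data$sex == .env$sex)
  if (nrow(d) == 0) abort("no records to fit")
  if (length(unique(d$exposed)) < 2) {
    abort("exposure column is constant: no exposed (or no unexposed) records")
  }
  if (sum(d$event[d$exposed == 1]) == 0) {
    abort("no events in the exposed stratum: model not estimable")
  }
  if (sum(d$event[d$exposed == 0]) == 0) {
    abort("no events in the unexposed stratum: model not estimable")
  }
  d <- mutate(d,
              entry_age = .data$age_covariate - .data$start,
              # droplevels: degenerate test cohorts may not populate all
              # Charlson categories; absent levels must not enter the design
              charlson_category = droplevels(
                factor(.data$charlson_category, levels = charlson_levels())))
  if (exposure_coding == "by_site") {
    empty <- d |>
      filter(.data$exposed == 1L) |>
      group_by(.data$site) |>
      summarise(events = sum(.data$event), .groups = "drop") |>
      filter(.data$events == 0)
    if (nrow(empty) > 0) {
      if (!drop_empty_sites) {
        abort(paste0("no events for site stratum: ",
                     paste(empty$site, collapse = ", ")))
      }
      warn(paste0("dropping exposed person-time (no deaths) for site(s): ",
                  paste(empty$site, collapse = ", ")))
      d <- filter(d, !(.data$exposed == 1L & .data$site %in% empty$site))
    }
    d <- mutate(d, exposure = factor(
      dplyr::if_else(.data$exposed == 1L, .data$site, "none"),
      levels = c("none", intersect(site_hierarchy()$site, unique(d$site)))))
    rhs <- "exposure"
  } else {
    rhs <- "exposed"
  }
  # adjustment terms that are constant in a degenerate cohort are dropped
  if (stats::var(d$entry_age) > 0) rhs <- c(rhs, "entry_age")
  if (nlevels(d$charlson_category) > 1) rhs <- c(rhs, "charlson_category")
  # pooled-sex fits stratify the baseline hazard by sex
  if (length(unique(d$sex)) > 1) rhs <- c(rhs, "strata(sex)")
  fml <- stats::as.formula(paste("survival::Surv(start, stop, event) ~",
                                 paste(rhs, collapse = " + ")))
  fit <- survival::coxph(fml, data = d, cluster = cluster_id,
                         ties = "breslow", x = FALSE, y = FALSE)
  if (any(is.na(coef(fit)))) {
    abort(paste0("collinear covariates: ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }

  sm <- summary(fit)$coefficients
  beta <- sm[, "coef"]
  se <- sm[, "robust se"]
  terms <- rownames(sm)
  is_exp <- grepl("^expos", terms)
  est <- tibble(
    sex = if (is.null(sex)) "all" else sex,
    term = terms,
    site = dplyr::case_when(
      terms == "exposed" ~ "any",
      grepl("^exposure", terms) ~ sub("^exposure", "", terms),
      TRUE ~ NA_character_
    ),
    kind = dplyr::if_else(is_exp, "exposure", "covariate"),
    beta = unname(beta),
    se = unname(se),
    hr = exp(unname(beta)),
    ci_low = exp(unname(beta) - 1.96 * unname(se)),
    ci_high = exp(unname(beta) + 1.96 * unname(se))
  )

  # reference ('typical' person) covariate means: baseline covariates of the
  # full cohort, i.e. the time-zero records, where nobody is yet exposed
  base <- filter(d, .data$start == 0)
  ref <- c(
    entry_age = mean(base$entry_age),
    setNames(
      vapply(charlson_levels()[-1],
             function(l) mean(base$charlson_category == l), numeric(1)),
      paste0("charlson_category", charlson_levels()[-1]))
  )

  structure(list(
    estimates = est,
    reference_means = ref,
    exposure_coding = exposure_coding,
    sex = if (is.null(sex)) "all" else sex,
    n_records = nrow(d),
    n_persons = length(unique(d$cluster_id)),
    n_events = sum(d$event),
    fit = fit
  ), class = "skelage_cox")
}

#' @export
print.skelage_cox <- function(x, ...) {
  cat(sprintf(
    "Time-dependent Cox fit (%s, %s): %d persons, %d records, %d deaths\n",
    x$sex, x$exposure_coding, x$n_persons, x$n_records, x$n_events))
  print(filter(x$estimates, .data$kind == "exposure"))
  invisible(x)
}

#' Tidy a skelage Cox fit
#'
#' @param x a `skelage_cox` object.
#' @param ... unused.
#' @return tibble of terms with `beta`, cluster-robust `se`, `hr` and 95%
#'   confidence limits.
#' @export
tidy.skelage_cox <- function(x, ...) x$estimates

#' One-line model summary
#' @param x a `skelage_cox` object.
#' @param ... unused.
#' @return tibble with record, person and event counts and concordance.
#' @export
glance.skelage_cox <- function(x, ...) {
  tibble(
    sex = x$sex,
    exposure_coding = x$exposure_coding,
    n_persons = x$n_persons,
    n_records = x$n_records,
    n_events = x$n_events,
    concordance = unname(x$fit$concordance["concordance"])
  )
}

#' Forest plot of fracture-mortality hazard ratios
#'
#' @param object a `skelage_cox` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.skelage_cox <- function(object, ...) {
  d <- filter(object$estimates, .data$kind == "exposure") |>
    mutate(site = factor(.data$site, levels = rev(site_hierarchy()$site)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hr, y = .data$site)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL,
                  title = "Fracture site and mortality",
                  subtitle = paste0(object$sex,
                                    ", adjusted for age and Charlson index"))
}

#' Schoenfeld residual check of proportional hazards
#'
#' Scaled Schoenfeld residuals against follow-up time with a per-covariate
#' slope test (zero slope = proportional hazards holds). Diagnostic only:
#' no refitting is triggered.
#'
#' @param fit a `skelage_cox` object.
#' @return list with `table` (tibble: term, chisq, df, p) and `residuals`
#'   (tibble: time, term, residual) suitable for plotting.
#' @export
schoenfeld_check <- function(fit) {
  if (!inherits(fit, "skelage_cox")) abort("fit must be a skelage_cox object")
  if (fit$n_events < 10) {
    warn("fewer than 10 events: Schoenfeld diagnostics are unstable")
  }
  zph <- survival::cox.zph(fit$fit, transform = "km", terms = FALSE)
  tab <- as_tibble(zph$table, rownames = "term") |>
    rename(p_value = "p")
  res <- as_tibble(as.data.frame(zph$y)) |>
    mutate(time = zph$time) |>
    tidyr::pivot_longer(-"time", names_to = "term",
                        values_to = "residual")
  list(table = tab, residuals = res)
}

#' Deliberately naive from-entry exposure fit (immortal time bias demo)
#'
#' Mis-specifies the exposure by treating every person who ever fractures as
#' exposed from study entry, collapsing each person to a single record with
#' baseline covariates. Pre-fracture survival time is thereby credited to
#' the exposed group ("immortal time"), diluting the estimate towards or
#' below the null. Returned for side-by-side comparison with [fit_cox()];
#' never for inference.
#'
#' @inheritParams fit_cox
#' @return a `skelage_cox` object flagged with
#'   `exposure_coding = "naive_from_entry"`.
#' @export
naive_fit_for_bias_demo <- function(records, sex = NULL) {
  d <- records
  if (!is.null(sex)) d <- filter(d, .data$sex == .env$sex)
  ever <- d |>
    group_by(.data$person_id) |>
    summarise(
      stop = max(.data$stop),
      event = max(.data$event),
      exposed = max(.data$exposed),
      entry_age = .data$age_covariate[which.min(.data$start)] -
        min(.data$start),
      charlson_category = .data$charlson_category[which.min(.data$start)],
      sex = .data$sex[1],
      .groups = "drop"
    ) |>
    mutate(charlson_category = droplevels(
      factor(.data$charlson_category, levels = charlson_levels())))
  if (sum(ever$exposed) == 0) abort("no fractured persons: no exposed group")
  rhs <- "exposed"
  if (stats::var(ever$entry_age) > 0) rhs <- c(rhs, "entry_age")
  if (nlevels(ever$charlson_category) > 1) rhs <- c(rhs, "charlson_category")
  if (length(unique(ever$sex)) > 1) rhs <- c(rhs, "strata(sex)")
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(stop, event) ~",
                            paste(rhs, collapse = " + "))),
    data = ever, ties = "breslow")
  sm <- summary(fit)$coefficients
  beta <- sm["exposed", "coef"]
  se <- sm["exposed", "se(coef)"]
  est <- tibble(
    sex = if (is.null(sex)) "all" else sex,
    term = "exposed", site = "any", kind = "exposure",
    beta = beta, se = se, hr = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se)
  )
  structure(list(
    estimates = est, reference_means = NULL,
    exposure_coding = "naive_from_entry",
    sex = if (is.null(sex)) "all" else sex,
    n_records = nrow(ever), n_persons = nrow(ever),
    n_events = sum(ever$event), fit = fit
  ), class = "skelage_cox")
}
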