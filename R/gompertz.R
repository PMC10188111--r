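#' Gompertz mortality parameters
#'
#' The Gompertz law writes the mortality hazard at age `t` as
#' `h(t) = B * exp(k * t)`, or on the log scale `log h(t) = a + b * t` with
#' `a = log(B)` and `b = k`. Between roughly ages 50 and 95 human mortality
#' follows this law closely.
#'
#' @param a log hazard at age 0.
#' @param b per-year slope of the log hazard.
#' @param sex optional sex label.
#' @param r_squared optional fit quality (from [fit_gompertz()]).
#' @return a `gompertz_params` list.
#' @export
gompertz_params <- function(a, b, sex = NA_character_, r_squared = NA_real_) {
  if (!is.finite(a)) abort("a must be finite")
  if (!is.finite(b) || b < 0) abort("b must be finite and non-negative")
  structure(list(a = a, b = b, sex = sex, r_squared = r_squared,
                 closed_form_ok = b > 0),
            class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("Gompertz(a = %.4f [B = %.3g], b = %.4f)%s\n", x$a, exp(x$a),
              x$b,
              if (!is.na(x$sex)) paste0(" [", x$sex, "]") else ""))
  invisible(x)
}

#' Fit Gompertz parameters to a lifetable
#'
#' Least-squares fit of `log(rate) = a + b * age` over the given age span,
#' the span over which the log-linearity of human mortality is empirically
#' excellent.
#'
#' @param lifetable tibble with columns `age`, `sex`, `rate`.
#' @param sex which sex to fit.
#' @param age_lo,age_hi age span of the fit.
#' @return a [gompertz_params()] object with `r_squared` filled in. A
#'   zero-slope (constant-rate) table returns `b = 0` with
#'   `closed_form_ok = FALSE`, signalling that the closed-form life
#'   expectancy is unavailable and the numeric path must be used.
#' @export
fit_gompertz <- function(lifetable, sex, age_lo = 50, age_hi = 95) {
  lt <- filter(lifetable, .data$sex == .env$sex,
               .data$age >= age_lo, .data$age <= age_hi)
  if (nrow(lt) < 2) abort("lifetable does not cover the requested age span")
  if (any(lt$rate <= 0)) abort("lifetable rates must be strictly positive")
  fit <- lm(log(rate) ~ age, data = lt)
  b <- unname(coef(fit)["age"])
  if (abs(b) < 1e-12) b <- 0
  # suppressWarnings: summary.lm warns on an exactly log-linear table
  r2 <- suppressWarnings(summary(fit)$r.squared)
  gompertz_params(a = unname(coef(fit)["(Intercept)"]), b = b, sex = sex,
                  r_squared = r2)
}

#' Scaled exponential integral exp(x) * E1(x)
#'
#' `E1(x) = integral_x^inf exp(-u)/u du`. The product `exp(x) * E1(x)` is
#' the quantity the Gompertz life-expectancy formula needs; computing it as
#' one scaled product avoids overflow of `exp(x)` and underflow of `E1(x)`
#' at old ages, where `x` is large. Series expansion for `x <= 1`, modified
#' Lentz continued fraction for `x > 1`.
#'
#' @param x positive numeric vector.
#' @return `exp(x) * E1(x)`, same length as `x`.
#' @export
expint_e1_scaled <- function(x) {
  if (any(x <= 0)) abort("expint_e1_scaled requires x > 0")
  out <- numeric(length(x))
  small <- x <= 1
  if (any(small)) {
    xs <- x[small]
    # E1(x) = -gamma - log(x) + sum_{n>=1} (-1)^(n+1) x^n / (n * n!)
    euler_gamma <- 0.577215664901532860606512
    s <- numeric(length(xs))
    term <- rep(1, length(xs))
    for (n in 1:30) {
      term <- term * (-xs) / n
      s <- s - term / n
      if (all(abs(term / n) < 1e-17)) break
    }
    out[small] <- exp(xs) * (-euler_gamma - log(xs) + s)
  }
  if (any(!small)) {
    xl <- x[!small]
    # exp(x) E1(x) = 1/(x + 1 - 1^2/(x + 3 - 2^2/(x + 5 - ...)))
    tiny <- 1e-30
    f <- rep(tiny, length(xl))
    C <- f
    D <- rep(0, length(xl))
    for (n in 0:200) {
      an <- if (n == 0) 1 else -n^2
      bn <- xl + 2 * n + 1
      D <- bn + an * D
      D[D == 0] <- tiny
      C <- bn + an / C
      C[C == 0] <- tiny
      D <- 1 / D
      delta <- C * D
      f <- f * delta
      if (all(abs(delta - 1) < 1e-15)) break
    }
    out[!small] <- f
  }
  out
}

#' Closed-form Gompertz remaining life expectancy
#'
#' For a Gompertz hazard `h(t) = exp(a + b t)`, the expected remaining
#' lifetime at age `z` is `(1/b) * exp(G) * E1(G)` with
#' `G = exp(a + b z) / b`, where `E1` is the exponential integral. The
#' formula follows from substituting `u = G exp(b t)` in
#' `integral_0^inf exp(-G (exp(b t) - 1)) dt`.
#'
#' @param params a [gompertz_params()] object with `b > 0`.
#' @param z age (years), scalar or vector.
#' @return expected remaining years, same length as `z`.
#' @export
#' @examples
#' p <- gompertz_params(a = log(1.89e-5), b = 0.1)
#' remaining_le_closed(p, 70)  # about 14.7 years
remaining_le_closed <- function(params, z) {
  if (!inherits(params, "gompertz_params")) {
    abort("params must be a gompertz_params object")
  }
  if (!isTRUE(params$closed_form_ok) || params$b <= 0) {
    abort(paste("closed form requires b > 0;",
                "use remaining_le_numeric with the hazard function instead"))
  }
  if (any(z < 0)) abort("z must be non-negative")
  G <- exp(params$a + params$b * z) / params$b
  expint_e1_scaled(G) / params$b
}

#' Remaining life expectancy by numerical integration
#'
#' Computes `integral_0^inf S(t) dt` with
#' `S(t) = exp(-integral_0^t hazard(z + u) du)` by adaptive quadrature,
#' truncating at `z + horizon` where survival is numerically zero for any
#' human-scale hazard. This is the package's independent oracle for the
#' closed form and the engine behind lifetable life expectancy.
#'
#' @param hazard_fn vectorised function age -> hazard (per year).
#' @param z starting age in years.
#' @param horizon truncation horizon in years beyond `z`.
#' @param cumhaz_fn optional vectorised function t -> cumulative hazard over
#'   `[z, z + t]`; when supplied (e.g. in closed form for a step or
#'   log-linear hazard) it replaces the inner quadrature.
#' @return expected remaining years (scalar).
#' @export
remaining_le_numeric <- function(hazard_fn, z, horizon = 120,
                                 cumhaz_fn = NULL) {
  h_checked <- function(u) {
    h <- hazard_fn(z + u)
    if (any(!is.finite(h))) abort("non-finite hazard")
    h
  }
  if (is.null(cumhaz_fn)) {
    # cache the cumulative hazard at unit-spaced knots so every inner
    # quadrature spans at most one unit (robust to step hazards, whose
    # breakpoints for integer z then sit on the knots)
    knots <- seq(0, horizon, by = 1)
    seg <- vapply(seq_len(length(knots) - 1), function(i) {
      integrate(h_checked, knots[i], knots[i + 1], rel.tol = 1e-11,
                abs.tol = 1e-13, subdivisions = 500L)$value
    }, numeric(1))
    H_knot <- c(0, cumsum(seg))
    cumhaz_fn <- function(tt) {
      vapply(tt, function(t1) {
        if (t1 <= 0) return(0)
        i <- min(floor(t1), length(knots) - 1)  # whole units covered
        total <- H_knot[i + 1]
        if (t1 > knots[i + 1]) {
          total <- total + integrate(h_checked, knots[i + 1], t1,
                                     rel.tol = 1e-11, abs.tol = 1e-13,
                                     subdivisions = 500L)$value
        }
        total
      }, numeric(1))
    }
  }
  surv <- function(tt) exp(-cumhaz_fn(tt))
  # unit panels keep any hazard breakpoints on panel edges
  edges <- seq(0, horizon, by = 1)
  total <- 0
  for (i in seq_len(length(edges) - 1)) {
    total <- total + integrate(surv, edges[i], edges[i + 1],
                               rel.tol = 1e-9, abs.tol = 1e-12,
                               subdivisions = 500L)$value
  }
  # tail beyond the horizon under a constant-hazard approximation; zero to
  # numerical precision for any human-scale (increasing) hazard
  h_end <- hazard_fn(z + horizon)
  if (is.finite(h_end) && h_end > 0) {
    total <- total + surv(horizon) / h_end
  }
  total
}

# log-linear hazard interpolator over a lifetable for one sex: returns
# list(hazard_fn, cumhaz_fn(z, t)). Rates are anchored at integer ages and
# interpolated exponentially between them (exact for Gompertz-generated
# tables); beyond the last age the final slope is extrapolated.
lifetable_hazard <- function(lifetable, sex) {
  lt <- lifetable |>
    filter(.data$sex == .env$sex) |>
    arrange(.data$age)
  if (nrow(lt) < 2) abort("lifetable needs at least two ages per sex")
  if (any(diff(lt$age) != 1)) {
    abort("lifetable ages must be contiguous integers")
  }
  if (any(lt$rate <= 0)) abort("lifetable rates must be strictly positive")
  ages <- lt$age
  lr <- log(lt$rate)
  slopes <- diff(lr)  # per-year log-hazard slope per segment
  tail_slope <- mean(utils::tail(slopes, min(10, length(slopes))))
  hazard_fn <- function(age) {
    age <- pmax(age, ages[1])
    i <- pmin(pmax(findInterval(age, ages), 1), length(ages) - 1)
    over <- age > ages[length(ages)]
    h <- exp(lr[i] + slopes[i] * (age - ages[i]))
    if (any(over)) {
      h[over] <- exp(lr[length(ages)] +
                       tail_slope * (age[over] - ages[length(ages)]))
    }
    h
  }
  # exact integral of the exponential-interpolated hazard from a1 to a2
  cumhaz_seg <- function(a1, a2, h1_log, s) {
    if (abs(s) < 1e-12) return(exp(h1_log) * (a2 - a1))
    exp(h1_log) * (exp(s * (a2 - a1)) - 1) / s
  }
  cumhaz_fn <- function(a1, a2) {
    vapply(seq_along(a2), function(j) {
      lo <- a1
      hi <- a2[j]
      if (hi <= lo) return(0)
      total <- 0
      last_age <- ages[length(ages)]
      # tabulated span
      span_hi <- min(hi, last_age)
      cur <- lo
      while (cur < span_hi - 1e-12) {
        i <- min(max(findInterval(cur, ages), 1), length(ages) - 1)
        seg_end <- min(ages[i + 1], span_hi)
        total <- total + cumhaz_seg(cur, seg_end,
                                    lr[i] + slopes[i] * (cur - ages[i]),
                                    slopes[i])
        cur <- seg_end
      }
      # extrapolated tail
      if (hi > last_age) {
        lo2 <- max(lo, last_age)
        total <- total + cumhaz_seg(lo2, hi,
                                    lr[length(ages)] +
                                      tail_slope * (lo2 - last_age),
                                    tail_slope)
      }
      total
    }, numeric(1))
  }
  list(hazard_fn = hazard_fn, cumhaz_fn = cumhaz_fn,
       span = range(ages))
}

#' Remaining life expectancy from a lifetable
#'
#' Interpolates the tabulated annual rates log-linearly in age (exact when
#' the table was generated from a Gompertz law, the standard
#' constant-growth assumption otherwise), extrapolates the final slope
#' beyond the last tabulated age, and integrates survival numerically.
#'
#' @param lifetable tibble with columns `age`, `sex`, `rate`.
#' @param sex sex to use.
#' @param z age in years (within the tabulated span).
#' @return expected remaining years (scalar, vectorised over `z`).
#' @export
lifetable_le <- function(lifetable, sex, z) {
  lh <- lifetable_hazard(lifetable, sex)
  if (any(z < lh$span[1] | z > lh$span[2])) {
    abort(sprintf("z outside the tabulated span [%d, %d]",
                  lh$span[1], lh$span[2]))
  }
  vapply(z, function(zz) {
    remaining_le_numeric(lh$hazard_fn, zz,
                         cumhaz_fn = function(tt) lh$cumhaz_fn(zz, zz + tt))
  }, numeric(1))
}
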