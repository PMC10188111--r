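---
title: "Skeletal age: from fracture-mortality hazards to years of life lost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeletal age: from fracture-mortality hazards to years of life lost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelage)
library(dplyr)
```

## The problem

A fragility fracture — a fracture from minimal trauma, the clinical hallmark
of osteoporosis — carries a substantial excess mortality, yet that excess is
rarely part of doctor–patient communication because relative risks and
10-year probabilities are hard to internalise. *Skeletal age* re-expresses
the excess as an effective age: the chronological age at fracture plus the
years of life lost (YLL) attributable to the fracture. Telling a 60-year-old
man with a hip fracture that his skeleton is "66 years old" conveys the same
hazard ratio as "HR ≈ 2", in a currency everybody understands.

`skelage` implements this methodology as a tested pipeline over four
stages:

1. **Registry simulation** — a synthetic cohort with the statistical
   structure registry data are assumed to have, so every downstream stage is
   testable without access to restricted person-level data.
2. **Cohort building** — eligibility, fracture-analyzability and
   index-fracture rules, Charlson comorbidity scoring, and
   counting-process (start, stop] splitting of follow-up at the fracture
   date.
3. **Survival modelling** — time-dependent Cox regression of mortality on
   fracture exposure, adjusted for age and Charlson category, with
   cluster-robust variance.
4. **Gompertz transformation** — hazard ratios mapped to years of life lost
   and skeletal age through the Gompertz law of mortality, with confidence
   intervals inherited from the hazard-ratio limits.

## The model

### Time-dependent exposure and immortal time

Each person enters the cohort on 2001-01-01 aged 50+ and is followed to
death or 2016-12-31; incident low-trauma fractures are ascertained to
2014-12-31, guaranteeing at least two years of post-fracture mortality
follow-up. A fractured person's follow-up is split at the fracture date:
the pre-fracture interval is *unexposed* and carries the covariates at
study entry; the post-fracture interval is *exposed* and carries the
covariates at the time of fracture (Charlson score from the five-year
lookback before the fracture). Crediting the pre-fracture interval to the
unexposed experience is what removes immortal time bias: a person must
survive to their fracture date, and attributing that guaranteed survival to
the exposed group would dilute the hazard ratio. The package keeps a
deliberately naive from-entry coding (`naive_fit_for_bias_demo()`) purely
to demonstrate this artefact.

When several fracture sites are coded on the same day, only the most
proximal site counts (hip > femur > pelvis > vertebrae > humerus > rib >
clavicle > forearm > lower leg > knee > ankle > foot > hand); face, skull,
finger and toe fractures and high-trauma fractures are never analyzable.
Subsequent and recurrent fractures are out of scope by design: the first
analyzable fracture defines the exposure for the rest of follow-up.

### The Cox model and the age covariate

The hazard model is a proportional-hazards regression on the follow-up time
scale with the exposure indicator (any-fracture, or one indicator per
site), age, and Charlson category (0 / 1–2 / 3–4 / 5+, reference 0) as
covariates, Breslow tie handling, and variance clustered on person (each
fractured person contributes two correlated intervals). Pooled-sex fits
stratify the baseline hazard by sex.

One modelling choice deserves emphasis. The counting-process records carry
`age_covariate` = age at interval start (age at entry on unexposed records,
age at fracture on exposed records), but the *fitted* model adjusts for age
at study entry, recovered exactly as `age_covariate - start`. The reason is
structural: on the follow-up time scale every subject ages in lockstep, so
the exponential age progression `e^(k t)` common to the whole cohort is
absorbed by the nonparametric baseline hazard. The person-specific age
contribution is therefore the entry age. Putting the fracture-updated age
into the linear predictor instead adds the time-to-fracture to the exposed
intervals only — a quantity correlated with exposure — and demonstrably
biases the exposure coefficient downward (in simulation, a true hazard
ratio of 1.5 is recovered as ≈ 0.87 under that coding and as ≈ 1.50 under
entry-age adjustment). The package's parameter-recovery tests pin this
behaviour.

Proportional hazards are checked with scaled Schoenfeld residuals
(`schoenfeld_check()`), reported as a per-covariate slope test and residual
series for plotting; the check is diagnostic and never triggers automatic
refitting.

### The Gompertz law and years of life lost

Between roughly ages 50 and 95 the human mortality hazard is exponential in
age (the Gompertz law):

$$h(t) = B e^{k t} = e^{a + b t}, \qquad a = \log B,\; b = k.$$

The package uses the scale constants B ≈ 1.89e-5 (women) and 3.47e-5 (men).
The slope is not printed alongside those constants; the package's default
is k = 0.095/year, chosen once because it gives plausible late-life rates
with those B values (≈ 2.2%/yr for women at 75, ≈ 16%/yr at 95), and it is
always re-estimable from any supplied lifetable with `fit_gompertz()`
(least squares on log rate over ages 50–95).

Remaining life expectancy at age $z$ under a Gompertz hazard has the closed
form

$$e_G(z) = \frac{1}{b}\, e^{G} E_1(G), \qquad
  G = \frac{e^{a + b z}}{b},$$

where $E_1$ is the exponential integral. The published rendering of this
formula does not typeset cleanly, so the package derives the form above
(substitute $u = G e^{bt}$ in $\int_0^\infty
\exp\{-G(e^{bt}-1)\}\,dt$) and certifies it against an independent
adaptive-quadrature oracle (`remaining_le_numeric()`) to 1e-6 relative
error across ages 50–95 and slopes 0.08–0.11; in practice agreement is at
machine precision. The product $e^{G}E_1(G)$ is always computed as a single
scaled quantity — series for $G \le 1$, continued fraction for $G > 1$ —
because $e^G$ overflows and $E_1(G)$ underflows separately at old ages. No
installed library provides $E_1$, so the implementation is in-package and
tested against the integral representation
$e^x E_1(x) = \int_0^\infty e^{-t}/(t+x)\,dt$.

A proportional offset on the hazard is exactly an age shift:

$$e_G^{(r \cdot h)}(z) = e_G^{(h)}\!\left(z + \frac{\log r}{b}\right).$$

This identity is the mathematical heart of the effective-age idea — a
doubled hazard makes a 60-year-old's survival prospects those of a
$60 + \log(2)/b \approx 67$-year-old — and is verified to 1e-8 years in the
tests.

The transformation to skeletal age then proceeds as:

1. **Prognostic index.** For a risk profile (site, Charlson category) the
   index is the Cox linear predictor over the site indicator and Charlson
   indicators; the offset $\delta$ is the index minus the mean index of
   "typical" people. The reference population is the full analysis cohort
   at baseline — where nobody is yet fractured, so the site contribution of
   the reference is zero and, for a typical comorbidity profile,
   $\delta = \log \mathrm{HR}_{\text{site}}$. Age is deliberately excluded
   from the index; it enters through the evaluation age $z$.
2. **Years of life lost.** $\mathrm{YLL}(z) = e_{\text{pop}}(z) -
   e_G^{(a+\delta,\,b)}(z)$, where the population side comes from the
   lifetable (`lifetable_le()`) and the fracture side from the fitted
   Gompertz law with the offset. When the lifetable is itself
   Gompertz-generated — the default configuration — the two bases coincide
   exactly, and HR = 1 gives YLL = 0 identically.
3. **Skeletal age.** $\mathrm{SA}(z) = z + \mathrm{YLL}(z)$, with the 95%
   interval obtained by replacing the site's log hazard ratio by its
   confidence limits. Baseline-hazard and lifetable uncertainty are
   deliberately ignored: the interval reflects hazard-ratio uncertainty
   only.

Because remaining life expectancy is convex and decreasing in age, YLL at a
fixed hazard ratio shrinks as the age at fracture rises — the loss is most
pronounced in the youngest patients and converges in the oldest, and the
grids produced by `skeletal_age_table()` reproduce that pattern
structurally.

## The synthetic registry

`simulate_cohort()` generates the world the analysis assumes, with every
parameter fixed up front in `sim_config()`:

* 47.6% men; entry ages truncated-normal (men 63.9 ± 10.3, women
  65.5 ± 11.3, truncated at 50). The distributional form beyond mean/SD is
  an assumption; a truncated normal is the simplest shape consistent with
  them.
* Background mortality: Gompertz hazard in *chronological age* (so the
  printed B values give sensible adult rates), multiplied by a
  Charlson-category factor (1 / 1.6 / 2.8 / 4.5). Comorbidities are
  independent Bernoulli draws with a logistic age gradient (odds ×1.1–×3
  per decade, prevalences loosely matched to registry marginals);
  dependence between conditions is not modelled.
* Fractures: independent per-site exponential clocks. Site rates are the
  registry's site shares scaled so the analyzable low-trauma first-fracture
  process runs at 10.9/1000 person-years in men and 23.2/1000 in women;
  5% of events are high-trauma, and small rates at face/skull/finger/toe
  exercise the exclusion rules. Only the first analyzable low-trauma
  fracture is retained as exposure, after which the mortality hazard is
  multiplied by the site's true hazard ratio (defaults echo the consistent
  clinical ordering: hip 2.0 down to foot 1.0).
* 8% of persons carry a washout-period fracture history and are excluded by
  `apply_exclusions()`.
* Condition accrual between entry and fracture defaults to zero so that the
  generative mortality multiplier and the coded at-fracture Charlson agree
  exactly; an accrual rate can be switched on, at the price of a mild,
  realistic covariate misclassification.

What the generator does **not** emulate: calendar-time (secular) mortality
and incidence trends, seasonal or regional structure, dependence between
comorbidities, recurrent fractures, and real ICD-coding noise. A green
test therefore establishes that the *pipeline arithmetic and estimators*
behave as designed under the assumed structure — not that the synthetic
hazard ratios equal the published registry estimates, which cannot be
recomputed without the restricted source data and are instead covered by
property-based substitutes (parameter recovery, null coverage,
immortal-time direction, ordering and convergence of the skeletal-age
grid).

## Numerical choices

* Dates convert to years at 365.25 days/year everywhere; administrative
  censoring uses an end-of-day convention so the full study span is exactly
  16.0 years.
* A fracture recorded on the death date keeps its exposed interval with a
  one-day minimum length rather than being dropped.
* Lifetable rates are anchored at integer ages and interpolated
  *log-linearly* between them (exact for Gompertz-generated tables, the
  standard constant-growth assumption otherwise), with the final slope
  extrapolated beyond the last tabulated age. Treating the rates as flat
  over [age, age+1) instead understates the cumulative hazard by
  (e^k − 1)/k ≈ 5% and shifts life expectancies by ~0.3 years — enough to
  break the closed-form consistency the package promises.
* `remaining_le_numeric()` integrates survival over unit panels with the
  cumulative hazard cached at unit knots (robust to step hazards) and adds
  a constant-hazard tail correction beyond the 120-year horizon.
* Ties in the Cox partial likelihood use the Breslow approximation —
  standard for large registries and exact here, since simulated event times
  are continuous.
* Skeletal-age grids are written at one decimal year, the package's
  documented output precision; negative YLL (HR < 1) is reported as
  computed, with a warning, never clamped.

## Open design points, resolved

* **Charlson variant.** The original weights (MI 1 … metastatic disease 6,
  HIV/AIDS 6); hypertension and arrhythmias are carried in the vocabulary
  but score zero, as they are not classic components. The weights are a
  documented, swappable table (`charlson_weights()`).
* **One model per site vs a single multi-site model.** Both are provided
  (`exposure_coding = "any_fracture" | "by_site"`); with equal true site
  effects the two agree to within 0.02 on the log scale in the tests.
* **Age in the model.** Linear in entry age, for the structural reason
  given above; banded age would also be unbiased but the skeletal-age
  machinery needs no age coefficient at all.
* **Follow-up medians.** Two defensible definitions (total study span vs
  per-person median) differ in the source material; the simulator exposes
  the raw dates so either can be computed, and the package adjudicates
  neither.

## Limitations

The confidence intervals deliberately ignore baseline-hazard and lifetable
uncertainty. The synthetic cohort is a stated world, not a calibrated
digital twin: absolute synthetic mortality rates differ from the Danish
ones (the Gompertz slope and comorbidity multipliers are package choices),
so only quantities the pipeline is designed to recover — hazard ratios,
rate arithmetic, and the structure of the skeletal-age grid — should be
compared against published values. Recurrent fractures, treatment effects
and cause-specific mortality are out of scope.
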