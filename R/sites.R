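#' Fracture-site hierarchy
#'
#' The skeleton is ordered from the most proximal to the most distal site.
#' When several fractures are recorded on the same day only the most proximal
#' one defines the exposure; face, skull, finger and toe fractures are never
#' analyzable and are dropped together with high-trauma events.
#'
#' @return A tibble with one row per site: `site`, `rank` (1 = most
#'   proximal), `class` (`"proximal"`, `"distal"` or `"excluded"`) and
#'   `analyzable` (logical).
#' @export
#' @examples
#' site_hierarchy()
site_hierarchy <- function() {
  proximal <- c("hip", "femur", "pelvis", "vertebrae", "humerus", "rib",
                "clavicle")
  distal <- c("forearm", "lower_leg", "knee", "ankle", "foot", "hand")
  excluded <- c("face", "skull", "finger", "toe")
  tibble(
    site = c(proximal, distal, excluded),
    rank = seq_along(c(proximal, distal, excluded)),
    class = rep(c("proximal", "distal", "excluded"),
                c(length(proximal), length(distal), length(excluded))),
    analyzable = rep(c(TRUE, FALSE), c(length(proximal) + length(distal),
                                       length(excluded)))
  )
}

#' Charlson comorbidity weights
#'
#' Original Charlson weights over the condition vocabulary used throughout
#' the package. Hypertension and arrhythmias are carried in the vocabulary
#' (they are tabulated comorbidities) but are not classic Charlson components
#' and score 0.
#'
#' @return A tibble with columns `condition` and `weight`.
#' @export
charlson_weights <- function() {
  tibble(
    condition = c(
      "myocardial_infarction", "congestive_heart_failure",
      "peripheral_vascular_disease", "stroke", "dementia",
      "chronic_lung_disease", "rheumatologic_disease", "mild_liver_disease",
      "diabetes", "diabetes_with_complications", "hemiplegia",
      "renal_disease", "cancer", "moderate_severe_liver_disease",
      "metastatic_tumors", "hiv_aids", "hypertension", "arrhythmias"
    ),
    weight = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
               1L, 2L, 2L, 2L, 2L, 3L, 6L, 6L, 0L, 0L)
  )
}

#' Charlson category labels in display order
#' @keywords internal
charlson_levels <- function() c("0", "1-2", "3-4", "5+")

#' Map a Charlson index to its category
#' @param index integer vector of Charlson indices.
#' @return factor with levels `"0" < "1-2" < "3-4" < "5+"`.
#' @export
charlson_category <- function(index) {
  stopifnot(all(index >= 0))
  cut(index, breaks = c(-Inf, 0, 2, 4, Inf), labels = charlson_levels(),
      ordered_result = TRUE)
}

#' Charlson comorbidity index of a condition set
#'
#' Sums the weights of the conditions present and assigns the severity
#' category used in the analysis (0, 1-2, 3-4, 5+).
#'
#' @param conditions character vector of condition labels (may be empty), or
#'   a single `;`-separated string as stored in the cohort files.
#' @param weights weight table, by default [charlson_weights()].
#' @return A list with `index` (integer) and `category` (ordered factor).
#' @export
#' @examples
#' charlson_score(c("myocardial_infarction", "congestive_heart_failure"))
charlson_score <- function(conditions, weights = charlson_weights()) {
  conditions <- split_conditions(conditions)
  unknown <- setdiff(conditions, weights$condition)
  if (length(unknown) > 0) {
    abort(paste0("unknown condition label(s): ",
                 paste(unknown, collapse = ", ")))
  }
  idx <- sum(weights$weight[weights$condition %in% conditions])
  list(index = as.integer(idx), category = charlson_category(idx))
}

# vectorised index over a character vector of ';'-separated condition strings
charlson_index_str <- function(x, weights = charlson_weights()) {
  w <- setNames(weights$weight, weights$condition)
  x[is.na(x)] <- ""
  spl <- strsplit(x, ";", fixed = TRUE)
  out <- vapply(spl, function(cs) {
    cs <- cs[nzchar(cs)]
    if (length(cs) == 0) return(0L)
    wi <- w[cs]
    if (anyNA(wi)) {
      abort(paste0("unknown condition label(s): ",
                   paste(cs[is.na(wi)], collapse = ", ")))
    }
    as.integer(sum(wi))
  }, integer(1))
  out
}

split_conditions <- function(conditions) {
  if (length(conditions) == 1 && (is.na(conditions) || conditions == "")) {
    return(character(0))
  }
  if (length(conditions) == 1 && grepl(";", conditions, fixed = TRUE)) {
    conditions <- strsplit(conditions, ";", fixed = TRUE)[[1]]
  }
  conditions[nzchar(conditions)]
}
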