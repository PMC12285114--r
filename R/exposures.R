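#' Classify lifestyle factors as favorable or unfavorable
#'
#' Applies the six-factor unfavorable-lifestyle definition to one or more
#' lifestyle profiles and counts unfavorable factors into the three lifestyle
#' categories used throughout the package: favorable (0-1 unfavorable
#' factors), intermediate (2-4), and unfavorable (5-6).
#'
#' The six flags are:
#' \describe{
#'   \item{smoking}{current smoker, or former smoker who stopped because of
#'     illness.}
#'   \item{diet}{any of: not eating fresh fruit daily, not eating fresh
#'     vegetables daily, eating red meat daily or less than weekly.}
#'   \item{physical_activity}{total physical activity below the sex- and
#'     age-stratum median supplied in `pa_median` (MET-hours/day). Values
#'     exactly equal to the median count as favorable by default; set
#'     `pa_at_median_unfavorable = TRUE` to flip that convention.}
#'   \item{sleep}{sleeping less than 7 or more than 9 hours/day.}
#'   \item{bmi}{body-mass index below 18.5 or at/above 24.0 kg/m^2.}
#'   \item{waist}{waist circumference at/above 90 cm (men) / 85 cm (women).}
#' }
#'
#' @param profile data.frame with one row per individual and columns
#'   `smoking_status` (one of `"never"`, `"former_by_choice"`,
#'   `"former_by_illness"`, `"current"`), `eats_fruit_daily`,
#'   `eats_veg_daily` (logical), `red_meat_freq` (one of `"daily"`,
#'   `"weekly"`, `"less_than_weekly"`), `total_physical_activity`
#'   (MET-hours/day), `sleep_hours`, `bmi`, `waist_circumference`, `sex`
#'   (`"female"`/`"male"`).
#' @param pa_median numeric scalar or vector (recycled to rows): the median
#'   total physical activity of the individual's sex/age stratum.
#' @param pa_at_median_unfavorable logical; whether activity exactly at the
#'   stratum median is flagged unfavorable. Default `FALSE` ("lower half"
#'   read strictly).
#' @return data.frame with the six logical flag columns, `n_unfavorable`,
#'   and `category` (factor with levels favorable/intermediate/unfavorable).
#' @examples
#' p <- data.frame(smoking_status = "current", eats_fruit_daily = TRUE,
#'                 eats_veg_daily = TRUE, red_meat_freq = "weekly",
#'                 total_physical_activity = 30, sleep_hours = 8,
#'                 bmi = 22, waist_circumference = 80, sex = "male")
#' classify_lifestyle(p, pa_median = 20)
#' @export
classify_lifestyle <- function(profile, pa_median,
                               pa_at_median_unfavorable = FALSE) {
  required <- c("smoking_status", "eats_fruit_daily", "eats_veg_daily",
                "red_meat_freq", "total_physical_activity", "sleep_hours",
                "bmi", "waist_circumference", "sex")
  missing_cols <- setdiff(required, names(profile))
  if (length(missing_cols) > 0L) {
    stop("profile is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in required) {
    if (anyNA(profile[[col]])) {
      stop("profile column '", col, "' contains missing values; ",
           "no silent imputation is performed")
    }
  }
  smoking_levels <- c("never", "former_by_choice", "former_by_illness",
                      "current")
  if (!all(profile$smoking_status %in% smoking_levels)) {
    stop("smoking_status must be one of: ",
         paste(smoking_levels, collapse = ", "))
  }
  meat_levels <- c("daily", "weekly", "less_than_weekly")
  if (!all(profile$red_meat_freq %in% meat_levels)) {
    stop("red_meat_freq must be one of: ",
         paste(meat_levels, collapse = ", "))
  }
  if (!all(profile$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'")
  }
  stopifnot(all(profile$bmi > 0), all(profile$waist_circumference > 0),
            all(profile$sleep_hours >= 0), all(profile$sleep_hours <= 24),
            all(pa_median > 0))

  n <- nrow(profile)
  pa_median <- rep_len(pa_median, n)

  smoking <- profile$smoking_status %in% c("current", "former_by_illness")
  diet <- !profile$eats_fruit_daily | !profile$eats_veg_daily |
    profile$red_meat_freq %in% c("daily", "less_than_weekly")
  physical_activity <- if (pa_at_median_unfavorable) {
    profile$total_physical_activity <= pa_median
  } else {
    profile$total_physical_activity < pa_median
  }
  sleep <- profile$sleep_hours < 7 | profile$sleep_hours > 9
  bmi <- profile$bmi < 18.5 | profile$bmi >= 24.0
  waist <- ifelse(profile$sex == "male",
                  profile$waist_circumference >= 90,
                  profile$waist_circumference >= 85)

  n_unfavorable <- smoking + diet + physical_activity + sleep + bmi + waist
  category <- cut(n_unfavorable, breaks = c(-Inf, 1, 4, 6),
                  labels = c("favorable", "intermediate", "unfavorable"))
  data.frame(smoking = smoking, diet = diet,
             physical_activity = physical_activity, sleep = sleep,
             bmi = bmi, waist = waist,
             n_unfavorable = as.integer(n_unfavorable),
             category = category)
}

#' Stratify a continuous risk score into genetic-risk categories
#'
#' Ranks standardized polygenic scores and assigns quintile-based categories
#' (low = bottom quintile, intermediate = 2nd-4th quintile, high = top
#' quintile) or tertile-based categories (low/intermediate/high thirds).
#' Cutoffs are rank-based: category k ends at rank `ceiling(k * n / K)`,
#' with ties broken by stable input order, so the assignment is invariant to
#' any strictly monotone transform of the scores.
#'
#' @param scores numeric vector of (typically standardized) scores.
#' @param scheme `"quintile"` (default) or `"tertile"`.
#' @return list with `category` (factor low/intermediate/high aligned to
#'   `scores`) and `quantile_cutoffs` (score values at the category
#'   boundary ranks).
#' @examples
#' table(categorize_prs(rnorm(1000))$category)
#' @export
categorize_prs <- function(scores, scheme = c("quintile", "tertile")) {
  scheme <- match.arg(scheme)
  n <- length(scores)
  if (n == 0L) stop("scores is empty")
  if (length(unique(scores)) < 5L) {
    stop("need at least 5 distinct score values")
  }
  r <- rank(scores, ties.method = "first")
  k <- if (scheme == "quintile") 5L else 3L
  bounds <- ceiling(seq_len(k) * n / k)
  # slice index 1..k for each individual, then collapse to three categories
  slice <- findInterval(r, c(0L, bounds), left.open = TRUE,
                        rightmost.closed = TRUE)
  category <- if (scheme == "quintile") {
    cut(slice, breaks = c(0, 1, 4, 5),
        labels = c("low", "intermediate", "high"))
  } else {
    cut(slice, breaks = c(0, 1, 2, 3),
        labels = c("low", "intermediate", "high"))
  }
  ord <- order(r)
  cutoff_ranks <- bounds[-k]
  cutoffs <- scores[ord][cutoff_ranks]
  list(category = category, quantile_cutoffs = cutoffs)
}
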