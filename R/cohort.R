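#' Cohort demographic profile
#'
#' Marginals used by [generate_cohort()]. Defaults reproduce the combined
#' recruitment of the two intervention studies: 51 healthy adults, 57%
#' female, ages 19-77 with mean 46.3 (SD 17.5) years, and the reported
#' anthropometric means/SDs (weight 68.3 (11.5) kg, height 168.2 (8.0) cm,
#' waist 83.1 (9.7) cm). Truncation bounds for weight, height and waist are
#' wide physiological ranges, not observed extremes.
#'
#' @param n Number of participants.
#' @param prop_female Proportion female in `[0, 1]`.
#' @param age_mean,age_sd,age_range Age distribution (years), truncated to
#'   `age_range`.
#' @param weight_mean,weight_sd Weight (kg).
#' @param height_mean,height_sd Height (cm).
#' @param waist_mean,waist_sd Waist circumference (cm).
#' @return List of class `cohort_profile`.
#' @export
cohort_profile <- function(n = 51, prop_female = 0.57,
                           age_mean = 46.3, age_sd = 17.5,
                           age_range = c(19, 77),
                           weight_mean = 68.3, weight_sd = 11.5,
                           height_mean = 168.2, height_sd = 8.0,
                           waist_mean = 83.1, waist_sd = 9.7) {
  if (n < 1 || n != round(n)) stop("n must be a positive integer",
                                   call. = FALSE)
  if (prop_female < 0 || prop_female > 1) {
    stop("prop_female must lie in [0, 1]", call. = FALSE)
  }
  sds <- c(age_sd, weight_sd, height_sd, waist_sd)
  if (any(sds <= 0)) stop("standard deviations must be positive",
                          call. = FALSE)
  if (age_range[1] >= age_range[2]) {
    stop("age_range must be increasing", call. = FALSE)
  }
  structure(list(n = as.integer(n), prop_female = prop_female,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 height_mean = height_mean, height_sd = height_sd,
                 waist_mean = waist_mean, waist_sd = waist_sd),
            class = "cohort_profile")
}

#' Generate a simulated cohort
#'
#' Sex is assigned by deterministic rounding of `n * prop_female` (so the
#' default profile always yields 29 of 51 female, i.e. 57%) and then
#' shuffled over participants; age, weight, height and waist are drawn from
#' truncated normal distributions with the profile's means and SDs. BMI is
#' derived as weight / height(m)^2.
#'
#' @param profile A [cohort_profile()].
#' @param seed Integer seed.
#' @return `data.frame` with columns `participant_id`, `sex`, `age`,
#'   `weight_kg`, `height_cm`, `waist_cm`, `bmi`.
#' @examples
#' cohort <- generate_cohort(cohort_profile(n = 5), seed = 1)
#' @export
generate_cohort <- function(profile = cohort_profile(), seed) {
  stopifnot(inherits(profile, "cohort_profile"))
  set.seed(seed)
  n <- profile$n
  n_female <- round(profile$prop_female * n)
  sex <- sample(rep(c("F", "M"), c(n_female, n - n_female)))
  age <- rtruncnorm(n, profile$age_mean, profile$age_sd,
                    profile$age_range[1], profile$age_range[2])
  weight <- rtruncnorm(n, profile$weight_mean, profile$weight_sd, 40, 130)
  height <- rtruncnorm(n, profile$height_mean, profile$height_sd, 140, 205)
  waist <- rtruncnorm(n, profile$waist_mean, profile$waist_sd, 55, 135)
  data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    sex = sex,
    age = age,
    weight_kg = weight,
    height_cm = height,
    waist_cm = waist,
    bmi = weight / (height / 100)^2,
    stringsAsFactors = FALSE)
}
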