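#' Daily menu plans of the dietary intervention
#'
#' Six daily menu plans, each with a breakfast, lunch, afternoon-snack and
#' dinner slot, emulating conventional UK eating patterns. Plans 1-3 form
#' experimental period 1 (validation foods with published biomarkers);
#' plans 4-6 form experimental period 2 (discovery foods: several legume
#' forms, curry, toasted/baked products, berries and tomato, and a
#' low-calorie sweetened beverage). Food identities follow the intervention's
#' food descriptions; exact gram amounts are deliberately not encoded (they
#' belong to portion-size configuration, not the design structure).
#'
#' @return Named list of six plans; each plan is a list with `plan_id`,
#'   `period`, and `meals`, a `data.frame` with columns `slot`, `food`,
#'   `food_group`, `preparation`.
#' @export
menu_plans <- function() {
  mk <- function(plan_id, period, ...) {
    rows <- list(...)
    meals <- do.call(rbind, lapply(rows, function(r) {
      data.frame(slot = r[[1]], food = r[[2]], food_group = r[[3]],
                 preparation = r[[4]], stringsAsFactors = FALSE)
    }))
    list(plan_id = plan_id, period = period, meals = meals)
  }
  plans <- list(
    mk(1L, 1L,
       list("breakfast", "wholegrain cereal", "grains", "with milk"),
       list("lunch", "salmon sandwich", "fish", "cold"),
       list("snack", "orange juice", "fruit", "pasteurized"),
       list("dinner", "chicken casserole", "meat", "ready meal")),
    mk(2L, 1L,
       list("breakfast", "porridge oats", "grains", "boiled with milk"),
       list("lunch", "ham sandwich", "meat", "cold"),
       list("snack", "grapes", "fruit", "raw"),
       list("dinner", "beef stew", "meat", "stewed")),
    mk(3L, 1L,
       list("breakfast", "wholemeal bread", "grains", "untoasted"),
       list("lunch", "tomato soup", "berries_tomato", "canned"),
       list("snack", "raisins", "fruit", "dried"),
       list("dinner", "garden peas", "legumes", "boiled")),
    mk(4L, 2L,
       list("breakfast", "wholegrain cereal", "grains", "with milk"),
       list("lunch", "tomato pasta", "berries_tomato", "boiled"),
       list("snack", "strawberries", "berries_tomato", "raw"),
       list("dinner", "garden peas", "legumes", "boiled")),
    mk(5L, 2L,
       list("breakfast", "toasted wholemeal bread", "heated", "toasted"),
       list("lunch", "baked beans", "legumes", "canned, heated"),
       list("snack", "peanuts", "legumes", "roasted"),
       list("dinner", "chicken curry", "curry", "cooked with clove spice")),
    mk(6L, 2L,
       list("breakfast", "porridge oats", "grains", "boiled with milk"),
       list("lunch", "meat pie", "heated", "oven baked"),
       list("snack", "low-calorie beverage", "low_cal_beverage", "carbonated"),
       list("dinner", "tofu", "legumes", "stir fried"))
  )
  names(plans) <- paste0("plan", 1:6)
  plans
}

## Meal-slot time windows in hours of day: 2 h for main meals, 30 min for
## the afternoon snack.
meal_windows <- function() {
  data.frame(slot = c("breakfast", "lunch", "snack", "dinner"),
             start = c(8, 12, 16, 18),
             end = c(10, 14, 16.5, 20),
             stringsAsFactors = FALSE)
}

#' Randomize participants for the 3-week discovery study (Study 2)
#'
#' Each participant is assigned, uniformly and independently, one of the 12
#' order-3 Latin squares (3 daily menu plans x 3 experimental weeks) and an
#' independent random order for the three "Pre"-day dinners. The dinner
#' order is drawn from a sub-seed stream derived from the master seed, so
#' the two draws are independent but both reproducible.
#'
#' @param participant_ids Character vector of unique ids.
#' @param seed Integer master seed.
#' @return List of `study_assignment` objects with fields `participant_id`,
#'   `study` (2), `square_index` (1-12), `square` (3x3 matrix) and
#'   `dinner_order` (permutation of 1:3).
#' @export
randomize_study2 <- function(participant_ids, seed) {
  check_ids(participant_ids)
  squares <- enumerate_latin_squares(3)
  n <- length(participant_ids)
  set.seed(seed)
  idx <- sample.int(length(squares), n, replace = TRUE)
  set.seed(derive_seed(seed, "dinner-order"))
  dinner <- lapply(seq_len(n), function(i) sample.int(3L))
  lapply(seq_len(n), function(i) {
    structure(list(participant_id = participant_ids[i], study = 2L,
                   square_index = idx[i], square = squares[[idx[i]]],
                   dinner_order = dinner[[i]]),
              class = "study_assignment")
  })
}

#' Randomize participants for the 2-week crossover study (Study 1)
#'
#' Participants are assigned uniformly to one of two crossover arms for the
#' "Pre"-day dinner: standardized evening meal first, or low-polyphenol meal
#' of their own choice first; every participant experiences both dinners
#' over the two weeks.
#'
#' @inheritParams randomize_study2
#' @return List of `study_assignment` objects with `crossover_arm` in
#'   `"standardized_first"` / `"low_polyphenol_first"`.
#' @export
randomize_study1 <- function(participant_ids, seed) {
  check_ids(participant_ids)
  set.seed(seed)
  arms <- sample(c("standardized_first", "low_polyphenol_first"),
                 length(participant_ids), replace = TRUE)
  lapply(seq_along(participant_ids), function(i) {
    structure(list(participant_id = participant_ids[i], study = 1L,
                   crossover_arm = arms[i]),
              class = "study_assignment")
  })
}

check_ids <- function(ids) {
  if (length(ids) == 0) stop("no participant ids supplied", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate participant id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  invisible(ids)
}

#' @export
print.study_assignment <- function(x, ...) {
  cat("<study_assignment> ", x$participant_id, " (study ", x$study, "): ",
      if (x$study == 2L) {
        paste0("square ", x$square_index, ", dinner order ",
               paste(x$dinner_order, collapse = "-"))
      } else x$crossover_arm, "\n", sep = "")
  invisible(x)
}

#' Build the meal and urine-collection schedule for one experimental week
#'
#' Day 0 is the "Pre" day (a pre-determined dinner only), days 1-3 are the
#' experimental days (four meal slots each, with the four scheduled daytime
#' urine types plus the open-ended post-dinner series), and day 4 is the
#' "Post" day (first morning void and fasting sample only). For Study 2 the
#' menu-plan order over days 1-3 is the assigned Latin square's row for the
#' requested week (plans 4-6); for Study 1 plans 1-3 are eaten in the same
#' fixed order both weeks.
#'
#' @param assignment A `study_assignment`.
#' @param week Week number: 1-2 for Study 1, 1-3 for Study 2.
#' @param plans Menu plan list, default [menu_plans()].
#' @return List with `meals` (`data.frame`: `day`, `slot`, `plan_id`,
#'   `food`, `food_group`, `window_start`, `window_end`) and `urine`
#'   (`data.frame`: `day`, `sample_type`).
#' @export
build_week_schedule <- function(assignment, week, plans = menu_plans()) {
  stopifnot(inherits(assignment, "study_assignment"))
  max_week <- if (assignment$study == 2L) 3L else 2L
  if (!week %in% seq_len(max_week)) {
    stop("week must be in 1..", max_week, " for study ", assignment$study,
         call. = FALSE)
  }
  plan_ids <- if (assignment$study == 2L) {
    assignment$square[week, ] + 3L
  } else {
    1:3
  }
  windows <- meal_windows()
  meals <- do.call(rbind, lapply(1:3, function(day) {
    key <- paste0("plan", plan_ids[day])
    if (!key %in% names(plans)) {
      stop("missing menu plan ", plan_ids[day], call. = FALSE)
    }
    p <- plans[[key]]
    m <- p$meals
    m$day <- day
    m$plan_id <- p$plan_id
    m <- merge(m, windows, by = "slot")
    m[order(m$start), c("day", "slot", "plan_id", "food", "food_group",
                        "start", "end")]
  }))
  names(meals)[names(meals) %in% c("start", "end")] <-
    c("window_start", "window_end")
  pre_dinner <- if (assignment$study == 2L) {
    paste0("pre-day dinner option ", assignment$dinner_order[week])
  } else if (identical(assignment$crossover_arm, "standardized_first") ==
             (week == 1)) {
    "standardized evening meal"
  } else {
    "low polyphenol evening meal"
  }
  meals <- rbind(
    data.frame(day = 0L, slot = "dinner", plan_id = NA_integer_,
               food = pre_dinner, food_group = "pre_dinner",
               window_start = 18, window_end = 20, stringsAsFactors = FALSE),
    meals)
  rownames(meals) <- NULL
  daytime <- c("FMV", "fasting", "post_breakfast", "post_lunch")
  urine <- rbind(
    expand.grid(day = 1:3, sample_type = c(daytime, "post_dinner_series"),
                stringsAsFactors = FALSE),
    data.frame(day = 4L, sample_type = c("FMV", "fasting"),
               stringsAsFactors = FALSE))
  urine <- urine[order(urine$day, match(urine$sample_type,
                                        c(daytime, "post_dinner_series"))), ]
  rownames(urine) <- NULL
  list(meals = meals, urine = urine)
}

#' Per-participant dietary compliance fraction
#'
#' Participants self-report the amount eaten of each provided item on the
#' five-level scale 0, 25, 50, 75 or 100%. The compliance fraction is the
#' mean fraction eaten per participant; the overall summary is the mean
#' over participants.
#'
#' @param records `data.frame` with columns `participant_id` and
#'   `amount_eaten_percent` (values in {0, 25, 50, 75, 100}).
#' @return List with `per_participant` (named numeric) and `overall`.
#' @examples
#' compliance_fraction(data.frame(participant_id = "P1",
#'                                amount_eaten_percent = c(100, 50)))
#' @export
compliance_fraction <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no compliance records supplied", call. = FALSE)
  }
  required <- c("participant_id", "amount_eaten_percent")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- !records$amount_eaten_percent %in% c(0, 25, 50, 75, 100)
  if (any(bad)) {
    stop("amount_eaten_percent outside the five-level scale in row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  per <- tapply(records$amount_eaten_percent / 100,
                records$participant_id, mean)
  per <- stats::setNames(as.numeric(per), names(per))
  list(per_participant = per, overall = mean(per))
}
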