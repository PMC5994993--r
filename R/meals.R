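#' Construct a validated meal-event table
#'
#' Meals act on the model as impulses: at each start time the stomach
#' compartment jumps by the meal amplitude (a glucose-equivalent quantity in
#' the same concentration-like units as the gut compartments, chosen so that
#' `kgut * qgut` has units mg dl^-1 min^-1). The meal class selects the gut
#' absorption rate: `"liquid"` meals empty with `kgut_liquid`, `"mixed"`
#' meals with the slower `kgut_mixed`, so one record may mix both classes.
#'
#' @param time_min Meal start times, minutes from the start of the record.
#' @param amplitude Non-negative impulse sizes added to the stomach
#'   compartment.
#' @param meal_class `"liquid"` or `"mixed"`, recycled if length 1.
#' @param label Optional free-text label per meal.
#' @return A tibble of class `cgm_meals`, sorted by `time_min`.
#' @export
#' @examples
#' meal_events(
#'   time_min = c(450, 1051, 1260),
#'   amplitude = c(50, 177, 316),
#'   meal_class = c("liquid", "mixed", "mixed")
#' )
meal_events <- function(time_min, amplitude, meal_class = "liquid",
                        label = NA_character_) {
  if (length(time_min) == 0L) {
    return(structure(
      tibble(
        time_min = numeric(), amplitude = numeric(),
        meal_class = character(), label = character()
      ),
      class = c("cgm_meals", class(tibble()))
    ))
  }
  meal_class <- rep_len(as.character(meal_class), length(time_min))
  label <- rep_len(as.character(label), length(time_min))
  if (!all(meal_class %in% c("liquid", "mixed"))) {
    abort("`meal_class` must be \"liquid\" or \"mixed\".")
  }
  if (any(!is.finite(time_min)) || any(!is.finite(amplitude))) {
    abort("Meal times and amplitudes must be finite.")
  }
  if (any(amplitude < 0)) abort("Meal amplitudes must be >= 0.")
  out <- tibble(
    time_min = as.numeric(time_min), amplitude = as.numeric(amplitude),
    meal_class = meal_class, label = label
  )
  out <- dplyr::arrange(out, .data$time_min)
  structure(out, class = c("cgm_meals", class(tibble())))
}
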