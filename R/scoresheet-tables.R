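# Declarative encoding of the INCNS scoresheet: 19 items in 5 categories,
# item weights 0-3, maximum total 44.
#
# Numeric rows are stored as ascending bins; `lower` is the lower bound of
# each bin after the first, at the row's printed precision (`digits`), and
# `points` has one entry per bin. Inputs are rounded to the printed precision
# before lookup, which makes the binning total and deterministic.

incns_numeric_items <- list(
  wbc = list(
    category = "inflammation", digits = 1L,
    lower = c(2.9, 4, 10.1, 25.1), points = c(2L, 1L, 0L, 1L, 2L)),
  temperature_ax = list(
    category = "inflammation", digits = 1L,
    lower = c(36, 38.5, 40.1), points = c(1L, 0L, 1L, 2L)),
  albumin = list(
    category = "nutrition", digits = 1L,
    lower = c(25, 35), points = c(2L, 1L, 0L)),
  age = list(
    category = "systemic_condition", digits = 0L,
    lower = c(45, 65, 75), points = c(0L, 1L, 2L, 3L)),
  heart_rate = list(
    category = "systemic_condition", digits = 0L,
    lower = c(40, 60, 101, 150), points = c(2L, 1L, 0L, 1L, 2L)),
  sbp = list(
    category = "systemic_condition", digits = 0L,
    lower = c(70, 90, 141, 200), points = c(2L, 1L, 0L, 1L, 2L)),
  glucose = list(
    category = "systemic_condition", digits = 1L,
    lower = c(2.2, 3.9, 11.2, 19.4), points = c(2L, 1L, 0L, 1L, 2L)),
  sodium = list(
    category = "systemic_condition", digits = 0L,
    lower = c(120, 130, 151, 160), points = c(2L, 1L, 0L, 1L, 2L)),
  potassium = list(
    category = "systemic_condition", digits = 1L,
    lower = c(2.5, 3.5, 5.6, 7.0), points = c(2L, 1L, 0L, 1L, 2L)),
  creatinine = list(
    category = "systemic_condition", digits = 0L,
    lower = c(44, 133, 172), points = c(1L, 0L, 1L, 2L)),
  bilirubin = list(
    category = "systemic_condition", digits = 1L,
    lower = c(34.2, 102.6), points = c(0L, 1L, 2L))
)

incns_enum_items <- list(
  arousal = list(
    category = "consciousness",
    levels = c(spontaneous = 0L, to_verbal = 1L, to_pain = 2L, none = 3L)),
  awareness = list(
    category = "consciousness",
    levels = c(correct_response = 0L, confused_response = 1L,
               nonreflex_movements = 2L, none = 3L)),
  pupillary_reflex = list(
    category = "neurologic_function",
    levels = c(bilateral_sensitive = 0L, unilateral_slow_absent = 2L,
               bilateral_slow_absent = 3L)),
  corneal_reflex = list(
    category = "neurologic_function",
    levels = c(bilateral_sensitive = 0L, unilateral_slow_absent = 2L,
               bilateral_slow_absent = 3L)),
  verbal = list(
    category = "neurologic_function",
    levels = c(accurate = 0L, confused_inappropriate = 1L,
               incomprehensible_none = 2L)),
  swallow = list(
    category = "neurologic_function",
    levels = c(wst_I_II = 0L, wst_III_IV_or_unable = 1L))
)

incns_categories <- c("inflammation", "nutrition", "consciousness",
                      "neurologic_function", "systemic_condition")

motor_pain_levels <- c(obeys = 0L, localizes_withdraws = 1L,
                       flexes_extends = 2L, none = 3L)
vent_interaction_levels <- c(above_rate = 2L, at_rate_or_apnea = 3L)

# Item registry: one row per scoresheet item, with the snapshot fields each
# item consumes (composite items read several fields).
incns_item_registry <- local({
  items <- c("wbc", "temperature_ax", "albumin", "arousal", "awareness",
             "pupillary_reflex", "corneal_reflex", "verbal", "motor",
             "swallow", "respiration", "age", "heart_rate", "sbp", "glucose",
             "sodium", "potassium", "creatinine", "bilirubin")
  category <- c(wbc = "inflammation", temperature_ax = "inflammation",
                albumin = "nutrition", arousal = "consciousness",
                awareness = "consciousness",
                pupillary_reflex = "neurologic_function",
                corneal_reflex = "neurologic_function",
                verbal = "neurologic_function", motor = "neurologic_function",
                swallow = "neurologic_function",
                respiration = "neurologic_function",
                age = "systemic_condition", heart_rate = "systemic_condition",
                sbp = "systemic_condition", glucose = "systemic_condition",
                sodium = "systemic_condition",
                potassium = "systemic_condition",
                creatinine = "systemic_condition",
                bilirubin = "systemic_condition")[items]
  max_points <- c(wbc = 2L, temperature_ax = 2L, albumin = 2L, arousal = 3L,
                  awareness = 3L, pupillary_reflex = 3L, corneal_reflex = 3L,
                  verbal = 2L, motor = 3L, swallow = 1L, respiration = 3L,
                  age = 3L, heart_rate = 2L, sbp = 2L, glucose = 2L,
                  sodium = 2L, potassium = 2L, creatinine = 2L,
                  bilirubin = 2L)[items]
  fields <- as.list(items)
  names(fields) <- items
  fields$motor <- c("motor_mode", "motor_strength_worst",
                    "motor_strength_unilateral_low", "motor_pain")
  fields$respiration <- c("intubated", "resp_rate", "vent_interaction")
  fields$verbal <- c("verbal", "intubated")
  data.frame(item = items, category = unname(category),
             max_points = unname(max_points),
             fields = I(unname(fields)), stringsAsFactors = FALSE)
})

#' INCNS scoresheet item registry
#'
#' Returns one row per scoresheet item: the item name, its category
#' (inflammation, nutrition, consciousness, neurologic function, systemic
#' condition), the item's maximum point value, and the snapshot fields the
#' item reads. The sum of `max_points` is 44, the maximum attainable total.
#'
#' @return A data.frame with columns `item`, `category`, `max_points` and a
#'   list column `fields`.
#' @export
#' @examples
#' sum(incns_items()$max_points) # 44
incns_items <- function() incns_item_registry
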