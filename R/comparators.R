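# Benchmark severity scores, transcribed from their original publications.
# APACHE II: 12 acute-physiology variables (worst value), age points, chronic
# health points; range 0-71. SAPS II: 17 variables; range 0-163.
# A second, independent transcription ships as JSON under inst/extdata and is
# diffed against these tables by the test suite.

apache2_numeric_items <- list(
  temperature_core = list(digits = 1L,
    lower = c(30, 32, 34, 36, 38.5, 39, 41),
    points = c(4L, 3L, 2L, 1L, 0L, 1L, 3L, 4L)),
  map = list(digits = 0L,
    lower = c(50, 70, 110, 130, 160), points = c(4L, 2L, 0L, 2L, 3L, 4L)),
  heart_rate = list(digits = 0L,
    lower = c(40, 55, 70, 110, 140, 180),
    points = c(4L, 3L, 2L, 0L, 2L, 3L, 4L)),
  resp_rate = list(digits = 0L,
    lower = c(6, 10, 12, 25, 35, 50), points = c(4L, 2L, 1L, 0L, 1L, 3L, 4L)),
  ph = list(digits = 2L,
    lower = c(7.15, 7.25, 7.33, 7.5, 7.6, 7.7),
    points = c(4L, 3L, 2L, 0L, 1L, 3L, 4L)),
  hco3 = list(digits = 1L,
    lower = c(15, 18, 22, 32, 41, 52), points = c(4L, 3L, 2L, 0L, 1L, 3L, 4L)),
  sodium = list(digits = 0L,
    lower = c(111, 120, 130, 150, 155, 160, 180),
    points = c(4L, 3L, 2L, 0L, 1L, 2L, 3L, 4L)),
  potassium = list(digits = 1L,
    lower = c(2.5, 3, 3.5, 5.5, 6, 7), points = c(4L, 2L, 1L, 0L, 1L, 3L, 4L)),
  creatinine_mgdl = list(digits = 1L,
    lower = c(0.6, 1.5, 2, 3.5), points = c(2L, 0L, 2L, 3L, 4L)),
  hematocrit = list(digits = 1L,
    lower = c(20, 30, 46, 50, 60), points = c(4L, 2L, 0L, 1L, 2L, 4L)),
  wbc = list(digits = 1L,
    lower = c(1, 3, 15, 20, 40), points = c(4L, 2L, 0L, 1L, 2L, 4L)),
  aa_gradient = list(digits = 0L,
    lower = c(200, 350, 500), points = c(0L, 2L, 3L, 4L)),
  pao2 = list(digits = 0L,
    lower = c(55, 61, 71), points = c(4L, 3L, 1L, 0L)),
  age = list(digits = 0L,
    lower = c(45, 55, 65, 75), points = c(0L, 2L, 3L, 5L, 6L))
)

saps2_numeric_items <- list(
  age = list(digits = 0L,
    lower = c(40, 60, 70, 75, 80), points = c(0L, 7L, 12L, 15L, 16L, 18L)),
  heart_rate = list(digits = 0L,
    lower = c(40, 70, 120, 160), points = c(11L, 2L, 0L, 4L, 7L)),
  sbp = list(digits = 0L,
    lower = c(70, 100, 200), points = c(13L, 5L, 0L, 2L)),
  temperature_core = list(digits = 1L, lower = 39, points = c(0L, 3L)),
  pf_ratio = list(digits = 0L,
    lower = c(100, 200), points = c(11L, 9L, 6L)),
  urine_output_l = list(digits = 3L,
    lower = c(0.5, 1), points = c(11L, 4L, 0L)),
  urea = list(digits = 1L, lower = c(10, 30), points = c(0L, 6L, 10L)),
  wbc = list(digits = 1L, lower = c(1, 20), points = c(12L, 0L, 3L)),
  potassium = list(digits = 1L, lower = c(3, 5), points = c(3L, 0L, 3L)),
  sodium = list(digits = 0L, lower = c(125, 145), points = c(5L, 0L, 1L)),
  hco3 = list(digits = 0L, lower = c(15, 20), points = c(6L, 3L, 0L)),
  bilirubin = list(digits = 1L,
    lower = c(68.4, 102.6), points = c(0L, 4L, 9L)),
  gcs = list(digits = 0L,
    lower = c(6, 9, 11, 14), points = c(26L, 13L, 7L, 5L, 0L))
)

saps2_chronic_points <- c(none = 0L, metastatic_cancer = 9L,
                          hematologic_malignancy = 10L, aids = 17L)
saps2_admission_points <- c(scheduled_surgical = 0L, medical = 6L,
                            unscheduled_surgical = 8L)

comparator_extra_fields <- c(
  "map", "temperature_core", "fio2", "pao2", "paco2", "aa_gradient", "ph",
  "hco3", "hematocrit", "urine_output_ml", "urea",
  "severe_organ_insufficiency", "acute_renal_failure", "admission_type",
  "saps_chronic", "gcs_eye", "gcs_verbal", "gcs_motor", "four_eye",
  "four_motor", "four_brainstem", "four_resp")

#' Assemble comparator inputs
#'
#' Extends a [patient_snapshot()] with the fields the comparator scores need
#' beyond the INCNS scoresheet: mean arterial pressure, core temperature
#' (falls back to axillary if absent), oxygenation (either `fio2`/`pao2`
#' [/`paco2`] or a direct `aa_gradient`), acid-base (`ph` or `hco3`),
#' hematocrit, 24 h urine output (mL), serum urea (mmol/L), chronic-health
#' and admission-type flags, and the GCS and FOUR component assessments.
#'
#' @param snapshot a [patient_snapshot()] or named list of snapshot fields.
#' @param ... comparator-only fields (see `comparator_extra_fields`).
#' @return An object of class `comparator_inputs` (also a valid snapshot
#'   carrier for INCNS scoring).
#' @export
comparator_inputs <- function(snapshot = NULL, ...) {
  extra <- list(...)
  unknown <- setdiff(names(extra), comparator_extra_fields)
  if (length(unknown) > 0L)
    stop("unknown comparator field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(snapshot)) snapshot <- patient_snapshot()
  if (!inherits(snapshot, "patient_snapshot") && is.list(snapshot))
    snapshot <- do.call(patient_snapshot,
                        snapshot[!vapply(snapshot, function(v)
                          length(v) != 1L || is.na(v), logical(1))])
  out <- unclass(snapshot)
  for (nm in comparator_extra_fields) out[[nm]] <- extra[[nm]] %||% NA
  validate_comparator_inputs(out)
  structure(out, class = c("comparator_inputs", "patient_snapshot"))
}

validate_comparator_inputs <- function(x) {
  rng <- list(gcs_eye = c(1, 4), gcs_verbal = c(1, 5), gcs_motor = c(1, 6),
              four_eye = c(0, 4), four_motor = c(0, 4),
              four_brainstem = c(0, 4), four_resp = c(0, 4))
  for (nm in names(rng)) {
    v <- x[[nm]]
    if (has_value(v)) {
      if (!is_scalar_number(v) || v != round(v) || v < rng[[nm]][1] ||
          v > rng[[nm]][2])
        stop(sprintf("%s must be an integer in [%d, %d]", nm, rng[[nm]][1],
                     rng[[nm]][2]), call. = FALSE)
    }
  }
  if (has_value(x$admission_type))
    assert_enum(x$admission_type, names(saps2_admission_points),
                "admission_type")
  if (has_value(x$saps_chronic))
    assert_enum(x$saps_chronic, names(saps2_chronic_points), "saps_chronic")
  if (has_value(x$fio2) && (x$fio2 < 0 || x$fio2 > 1))
    stop("fio2 must be a fraction in [0, 1]", call. = FALSE)
  invisible(x)
}

#' Glasgow Coma Scale total
#'
#' @param eye eye-opening component, 1-4.
#' @param verbal verbal component, 1-5.
#' @param motor motor component, 1-6.
#' @return Integer GCS total in \[3, 15\].
#' @export
#' @examples
#' score_gcs(4, 5, 6) # 15
score_gcs <- function(eye, verbal, motor) {
  comp <- c(eye = eye, verbal = verbal, motor = motor)
  lo <- c(1, 1, 1); hi <- c(4, 5, 6)
  if (any(!is.finite(comp)) || any(comp != round(comp)) || any(comp < lo) ||
      any(comp > hi))
    stop("GCS components out of range (eye 1-4, verbal 1-5, motor 1-6)",
         call. = FALSE)
  as.integer(sum(comp))
}

#' FOUR score total
#'
#' Full Outline of UnResponsiveness: eye, motor, brainstem and respiration
#' components, each 0-4.
#'
#' @param eye,motor,brainstem,respiration components, each an integer 0-4.
#' @return Integer FOUR total in \[0, 16\].
#' @export
score_four <- function(eye, motor, brainstem, respiration) {
  comp <- c(eye, motor, brainstem, respiration)
  if (any(!is.finite(comp)) || any(comp != round(comp)) || any(comp < 0) ||
      any(comp > 4))
    stop("FOUR components must be integers in [0, 4]", call. = FALSE)
  as.integer(sum(comp))
}

# Vectorized APACHE II core over a data.frame of comparator fields.
# Returns NA where required inputs are missing (policy applied by callers).
apache2_points_matrix <- function(df) {
  n <- nrow(df)
  col <- function(nm) if (nm %in% names(df)) df[[nm]] else rep(NA, n)
  num <- function(nm) as.numeric(col(nm))
  items <- c("temperature", "map", "heart_rate", "resp_rate", "oxygenation",
             "acid_base", "sodium", "potassium", "creatinine", "hematocrit",
             "wbc", "gcs", "age", "chronic_health")
  pts <- matrix(NA_integer_, n, length(items), dimnames = list(NULL, items))
  lk <- function(v, tab) bin_points(v, tab$lower, tab$points, tab$digits)

  temp <- num("temperature_core")
  temp[is.na(temp)] <- num("temperature_ax")[is.na(temp)]
  pts[, "temperature"] <- lk(temp, apache2_numeric_items$temperature_core)
  pts[, "map"] <- lk(num("map"), apache2_numeric_items$map)
  pts[, "heart_rate"] <- lk(num("heart_rate"), apache2_numeric_items$heart_rate)

  # respiratory rate: ventilated or not, the printed rate bins apply; for
  # intubated patients a recorded rate may be absent in this schema, in which
  # case the item is missing unless assume-normal applies
  pts[, "resp_rate"] <- lk(num("resp_rate"), apache2_numeric_items$resp_rate)

  # oxygenation: FiO2 >= 0.5 uses the A-a gradient, FiO2 < 0.5 uses PaO2.
  # A direct aa_gradient is honored; otherwise it is computed as
  # FiO2*713 - PaCO2/0.8 - PaO2.
  fio2 <- num("fio2"); pao2 <- num("pao2"); paco2 <- num("paco2")
  aa <- num("aa_gradient")
  aa_calc <- fio2 * 713 - paco2 / 0.8 - pao2
  aa[is.na(aa)] <- aa_calc[is.na(aa)]
  ox <- rep(NA_integer_, n)
  hi <- !is.na(fio2) & fio2 >= 0.5
  ox[hi] <- lk(aa[hi], apache2_numeric_items$aa_gradient)
  lo2 <- !is.na(fio2) & fio2 < 0.5
  ox[lo2] <- lk(pao2[lo2], apache2_numeric_items$pao2)
  pts[, "oxygenation"] <- ox

  ab <- lk(num("ph"), apache2_numeric_items$ph)
  hc <- lk(num("hco3"), apache2_numeric_items$hco3)
  ab[is.na(ab)] <- hc[is.na(ab)]
  pts[, "acid_base"] <- ab

  pts[, "sodium"] <- lk(num("sodium"), apache2_numeric_items$sodium)
  pts[, "potassium"] <- lk(num("potassium"), apache2_numeric_items$potassium)

  cr <- lk(num("creatinine") / 88.4, apache2_numeric_items$creatinine_mgdl)
  arf <- as.logical(col("acute_renal_failure"))
  dbl <- !is.na(arf) & arf
  cr[dbl] <- 2L * cr[dbl]
  pts[, "creatinine"] <- cr

  pts[, "hematocrit"] <- lk(num("hematocrit"), apache2_numeric_items$hematocrit)
  pts[, "wbc"] <- lk(num("wbc"), apache2_numeric_items$wbc)

  gcs <- num("gcs_eye") + num("gcs_verbal") + num("gcs_motor")
  pts[, "gcs"] <- as.integer(15 - gcs)

  pts[, "age"] <- lk(num("age"), apache2_numeric_items$age)

  soi <- as.logical(col("severe_organ_insufficiency"))
  adm <- as.character(col("admission_type"))
  ch <- rep(NA_integer_, n)
  ch[!is.na(soi) & !soi] <- 0L
  known <- !is.na(soi) & soi & !is.na(adm)
  ch[known & adm == "scheduled_surgical"] <- 2L
  ch[known & adm != "scheduled_surgical"] <- 5L
  pts[, "chronic_health"] <- ch

  pts
}

saps2_points_matrix <- function(df) {
  n <- nrow(df)
  col <- function(nm) if (nm %in% names(df)) df[[nm]] else rep(NA, n)
  num <- function(nm) as.numeric(col(nm))
  items <- c("age", "heart_rate", "sbp", "temperature", "oxygenation",
             "urine_output", "urea", "wbc", "potassium", "sodium", "hco3",
             "bilirubin", "gcs", "chronic_disease", "admission_type")
  pts <- matrix(NA_integer_, n, length(items), dimnames = list(NULL, items))
  lk <- function(v, tab) bin_points(v, tab$lower, tab$points, tab$digits)

  pts[, "age"] <- lk(num("age"), saps2_numeric_items$age)
  pts[, "heart_rate"] <- lk(num("heart_rate"), saps2_numeric_items$heart_rate)
  pts[, "sbp"] <- lk(num("sbp"), saps2_numeric_items$sbp)

  temp <- num("temperature_core")
  temp[is.na(temp)] <- num("temperature_ax")[is.na(temp)]
  pts[, "temperature"] <- lk(temp, saps2_numeric_items$temperature_core)

  # PaO2/FiO2 is scored only for ventilated (here: intubated) patients;
  # non-ventilated patients score 0 on this item
  intub <- as.logical(col("intubated"))
  pf <- num("pao2") / num("fio2")
  ox <- rep(NA_integer_, n)
  ox[!is.na(intub) & !intub] <- 0L
  vent <- !is.na(intub) & intub
  ox[vent] <- lk(pf[vent], saps2_numeric_items$pf_ratio)
  pts[, "oxygenation"] <- ox

  pts[, "urine_output"] <- lk(num("urine_output_ml") / 1000,
                              saps2_numeric_items$urine_output_l)
  pts[, "urea"] <- lk(num("urea"), saps2_numeric_items$urea)
  pts[, "wbc"] <- lk(num("wbc"), saps2_numeric_items$wbc)
  pts[, "potassium"] <- lk(num("potassium"), saps2_numeric_items$potassium)
  pts[, "sodium"] <- lk(num("sodium"), saps2_numeric_items$sodium)
  pts[, "hco3"] <- lk(num("hco3"), saps2_numeric_items$hco3)
  pts[, "bilirubin"] <- lk(num("bilirubin"), saps2_numeric_items$bilirubin)

  gcs <- num("gcs_eye") + num("gcs_verbal") + num("gcs_motor")
  pts[, "gcs"] <- lk(gcs, saps2_numeric_items$gcs)

  pts[, "chronic_disease"] <- enum_points(as.character(col("saps_chronic")),
                                          saps2_chronic_points)
  pts[, "admission_type"] <- enum_points(as.character(col("admission_type")),
                                         saps2_admission_points)
  pts
}

comparator_total <- function(pts, assume_normal, score_name) {
  miss <- is.na(pts)
  if (any(miss) && !assume_normal)
    stop_missing(colnames(pts)[miss], paste(score_name, "scoring"))
  pts[miss] <- 0L
  list(total = as.integer(sum(pts)), items = pts, imputed = miss)
}

#' APACHE II score
#'
#' Acute Physiology and Chronic Health Evaluation II: 12 worst-value
#' physiology items (0-4 points each, creatinine doubled in acute renal
#' failure, GCS item scored as 15 minus the GCS total), age points (0-6) and
#' chronic-health points (0-5). Range 0-71.
#'
#' Oxygenation uses the A-a gradient when FiO2 >= 0.5 and PaO2 otherwise;
#' acid-base uses arterial pH, falling back to serum bicarbonate.
#'
#' @param inputs a [comparator_inputs()] object.
#' @param assume_normal score missing items 0 and flag them instead of
#'   erroring.
#' @return List with `total`, per-item `points` and `imputed` flags.
#' @export
score_apache2 <- function(inputs, assume_normal = FALSE) {
  stopifnot(inherits(inputs, "comparator_inputs"))
  df <- comparator_to_df(inputs)
  pts <- apache2_points_matrix(df)[1L, ]
  res <- comparator_total(rbind(pts), assume_normal, "APACHE II")
  list(total = res$total, points = pts, imputed = res$imputed[1L, ])
}

#' SAPS II score
#'
#' Simplified Acute Physiology Score II: 17 variables with the published
#' irregular weights (age up to 18, GCS < 6 scoring 26, admission type,
#' chronic disease, oxygenation scored only in ventilated patients).
#' Range 0-163.
#'
#' @inheritParams score_apache2
#' @return List with `total`, per-item `points` and `imputed` flags.
#' @export
score_saps2 <- function(inputs, assume_normal = FALSE) {
  stopifnot(inherits(inputs, "comparator_inputs"))
  df <- comparator_to_df(inputs)
  pts <- saps2_points_matrix(df)[1L, ]
  res <- comparator_total(rbind(pts), assume_normal, "SAPS II")
  list(total = res$total, points = pts, imputed = res$imputed[1L, ])
}

comparator_to_df <- function(x) {
  all_fields <- c(incns_snapshot_fields, comparator_extra_fields)
  vals <- lapply(all_fields, function(nm) {
    v <- x[[nm]]
    if (is.null(v) || length(v) != 1L) NA else v
  })
  names(vals) <- all_fields
  as.data.frame(vals, stringsAsFactors = FALSE)
}
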