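# Worst-value abstraction: reduce a patient's time-stamped observations to
# the most deranged reading per scoresheet item within a window (24 h or
# 72 h from admission). "Most deranged" maximizes that item's points under
# the requested score; ties go to the earliest qualifying reading. Items are
# maximized independently, so the assembled snapshot may mix time points --
# the conventional worst-value abstraction of ICU severity scores.

obs_logical_fields <- c("intubated", "motor_strength_unilateral_low",
                        "severe_organ_insufficiency", "acute_renal_failure")
obs_character_fields <- c(names(snapshot_enum_values), "admission_type",
                          "saps_chronic")
obs_numeric_fields <- setdiff(c(incns_snapshot_fields, comparator_extra_fields),
                              c(obs_logical_fields, obs_character_fields))

# item -> consumed fields, and the vectorized points function, per score
score_item_fields <- function(score) {
  switch(score,
    incns = stats::setNames(incns_item_registry$fields,
                            incns_item_registry$item),
    gcs = list(gcs_eye = "gcs_eye", gcs_verbal = "gcs_verbal",
               gcs_motor = "gcs_motor"),
    four = list(four_eye = "four_eye", four_motor = "four_motor",
                four_brainstem = "four_brainstem", four_resp = "four_resp"),
    apache2 = list(
      temperature = c("temperature_core", "temperature_ax"), map = "map",
      heart_rate = "heart_rate", resp_rate = "resp_rate",
      oxygenation = c("fio2", "pao2", "paco2", "aa_gradient"),
      acid_base = c("ph", "hco3"), sodium = "sodium",
      potassium = "potassium",
      creatinine = c("creatinine", "acute_renal_failure"),
      hematocrit = "hematocrit", wbc = "wbc",
      gcs = c("gcs_eye", "gcs_verbal", "gcs_motor"), age = "age",
      chronic_health = c("severe_organ_insufficiency", "admission_type")),
    saps2 = list(
      age = "age", heart_rate = "heart_rate", sbp = "sbp",
      temperature = c("temperature_core", "temperature_ax"),
      oxygenation = c("intubated", "fio2", "pao2"),
      urine_output = "urine_output_ml", urea = "urea", wbc = "wbc",
      potassium = "potassium", sodium = "sodium", hco3 = "hco3",
      bilirubin = "bilirubin", gcs = c("gcs_eye", "gcs_verbal", "gcs_motor"),
      chronic_disease = "saps_chronic", admission_type = "admission_type"),
    stop("unknown score: ", score, call. = FALSE))
}

# Derangement points per item for a wide observation table. For GCS and FOUR
# (where lower components are worse) derangement is (component maximum -
# value), so maximization still selects the worst reading.
score_points_matrix <- function(df, score) {
  col <- function(nm) if (nm %in% names(df)) as.numeric(df[[nm]])
                      else rep(NA_real_, nrow(df))
  switch(score,
    incns = incns_points_matrix(df, warn_verbal_override = FALSE),
    apache2 = apache2_points_matrix(df),
    saps2 = saps2_points_matrix(df),
    gcs = {
      m <- cbind(gcs_eye = 4 - col("gcs_eye"),
                 gcs_verbal = 5 - col("gcs_verbal"),
                 gcs_motor = 6 - col("gcs_motor"))
      storage.mode(m) <- "integer"; m
    },
    four = {
      m <- cbind(four_eye = 4 - col("four_eye"),
                 four_motor = 4 - col("four_motor"),
                 four_brainstem = 4 - col("four_brainstem"),
                 four_resp = 4 - col("four_resp"))
      storage.mode(m) <- "integer"; m
    })
}

supported_scores <- c("incns", "apache2", "saps2", "gcs", "four")

# Long observations -> typed wide table, one row per (patient, time).
obs_to_wide <- function(obs) {
  obs <- data.table::as.data.table(obs)
  req <- c("patient_id", "time_h", "variable", "value")
  if (!all(req %in% names(obs)))
    stop("observations need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(obs$variable),
                 c(incns_snapshot_fields, comparator_extra_fields))
  if (length(bad) > 0L)
    stop("unknown observation variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(obs[, c("patient_id", "time_h", "variable")]))
    stop("duplicate (patient, time, variable) observation rows", call. = FALSE)
  wide <- data.table::dcast(obs, patient_id + time_h ~ variable,
                            value.var = "value")
  for (nm in intersect(names(wide), obs_numeric_fields))
    wide[[nm]] <- as.numeric(wide[[nm]])
  for (nm in intersect(names(wide), obs_logical_fields))
    wide[[nm]] <- as.logical(wide[[nm]])
  for (nm in intersect(names(wide), obs_character_fields))
    wide[[nm]] <- as.character(wide[[nm]])
  data.table::setorder(wide, patient_id, time_h)
  wide
}

# Core: per patient and per item, pick the in-window reading with maximal
# derangement points (earliest on ties) and assemble the worst-value fields.
worst_fields_table <- function(obs, window_hours, score,
                               assume_normal = FALSE) {
  stopifnot(window_hours %in% c(24, 72))
  score <- match.arg(score, supported_scores)
  wide <- if (data.table::is.data.table(obs) && "time_h" %in% names(obs) &&
              !"variable" %in% names(obs)) data.table::copy(obs)
          else obs_to_wide(obs)
  if (any(wide$time_h < 0))
    stop("observation before admission (negative time offset)", call. = FALSE)
  wide <- wide[wide$time_h <= window_hours, ]
  if (nrow(wide) == 0L)
    stop("no observations inside the ", window_hours, " h window",
         call. = FALSE)
  pm <- score_points_matrix(as.data.frame(wide), score)
  items <- score_item_fields(score)

  pids <- unique(wide$patient_id)
  out <- data.table::data.table(patient_id = pids)
  ptab <- matrix(NA_integer_, length(pids), length(items),
                 dimnames = list(NULL, names(items)))
  for (it in names(items)) {
    sel_dt <- data.table::data.table(pid = wide$patient_id, t = wide$time_h,
                                     p = pm[, it], row = seq_len(nrow(wide)))
    sel_dt <- sel_dt[!is.na(sel_dt$p), ]
    if (nrow(sel_dt) == 0L) next
    data.table::setorder(sel_dt, pid, -p, t)
    first <- sel_dt[, list(row = row[1L], p = p[1L]), by = "pid"]
    m <- match(first$pid, pids)
    ptab[m, it] <- first$p
    for (f in intersect(items[[it]], names(wide))) {
      if (!f %in% names(out))
        out[[f]] <- rep(wide[[f]][1L][NA], length(pids))
      out[[f]][m] <- wide[[f]][first$row]
    }
  }
  list(fields = out, points = ptab)
}

#' Most deranged snapshot over an observation window
#'
#' Reduces one patient's time-stamped observation series to the worst-value
#' snapshot for a 24 h or 72 h window from admission. Each scoresheet item is
#' maximized independently: the reading (within the closed window) that yields
#' the highest item points under `score` is selected, ties broken by the
#' earliest reading. Composite items (motor, respiration, oxygenation, ...)
#' are selected as a unit from a single time point.
#'
#' @param series long observations for one patient: data.frame with columns
#'   `time_h` (hours from admission), `variable`, `value` (and optionally
#'   `patient_id`).
#' @param window_hours 24 or 72. The boundary is closed: a reading at exactly
#'   `window_hours` counts.
#' @param score which score's derangement ordering to use: one of
#'   `"incns"`, `"apache2"`, `"saps2"`, `"gcs"`, `"four"`.
#' @param assume_normal if `TRUE`, items with no in-window reading are left
#'   missing for downstream assume-normal scoring instead of erroring.
#' @return A [patient_snapshot()] (for `"incns"`) or [comparator_inputs()]
#'   carrying the selected worst values.
#' @export
worst_snapshot <- function(series, window_hours, score = "incns",
                           assume_normal = FALSE) {
  series <- as.data.frame(series)
  if (!"patient_id" %in% names(series)) series$patient_id <- "patient"
  if (length(unique(series$patient_id)) != 1L)
    stop("worst_snapshot expects a single patient; see score_cohort",
         call. = FALSE)
  res <- worst_fields_table(series, window_hours, score, assume_normal)
  flds <- as.list(res$fields[1L, ])
  flds$patient_id <- NULL
  flds <- flds[!vapply(flds, function(v) is.na(v), logical(1))]
  if (!assume_normal) {
    miss <- names(res$points[1L, ])[is.na(res$points[1L, ])]
    if (length(miss) > 0L)
      stop_missing(miss, sprintf("%d h window (no scorable reading)",
                                 window_hours))
  }
  snap_fields <- flds[intersect(names(flds), incns_snapshot_fields)]
  extra <- flds[intersect(names(flds), comparator_extra_fields)]
  snap <- do.call(patient_snapshot, snap_fields)
  if (score %in% c("apache2", "saps2", "gcs", "four") || length(extra) > 0L)
    do.call(comparator_inputs, c(list(snapshot = snap), extra))
  else snap
}

#' Score a cohort of longitudinal observations
#'
#' Applies the worst-value abstraction ([worst_snapshot()]) to every patient
#' in a long observation table and totals the requested score.
#'
#' @param obs long observations: data.frame with columns `patient_id`,
#'   `time_h`, `variable`, `value`.
#' @param window_hours 24 or 72.
#' @param score one of `"incns"`, `"apache2"`, `"saps2"`, `"gcs"`, `"four"`.
#' @param assume_normal score items with no in-window reading as 0 (normal)
#'   and count them in `n_imputed`, instead of erroring.
#' @return A data.frame with `patient_id`, `score` (the total; for GCS and
#'   FOUR the conventional totals, not derangement points), `n_imputed`, and
#'   one `item_*` column of points per scoresheet item.
#' @export
score_cohort <- function(obs, window_hours, score = "incns",
                         assume_normal = FALSE) {
  score <- match.arg(score, supported_scores)
  res <- worst_fields_table(obs, window_hours, score, assume_normal)
  pts <- res$points
  miss <- is.na(pts)
  if (any(miss) && !assume_normal) {
    bad <- which(rowSums(miss) > 0)[1L]
    stop_missing(colnames(pts)[miss[bad, ]],
                 sprintf("patient %s, %d h window",
                         res$fields$patient_id[bad], window_hours))
  }
  pts[miss] <- 0L
  total <- rowSums(pts)
  # GCS / FOUR: convert derangement points back to the conventional totals
  if (score == "gcs") total <- 15 - total
  if (score == "four") total <- 16 - total
  out <- data.frame(patient_id = res$fields$patient_id,
                    score = as.integer(total),
                    n_imputed = as.integer(rowSums(miss)),
                    stringsAsFactors = FALSE)
  colnames(pts) <- paste0("item_", colnames(pts))
  cbind(out, as.data.frame(pts))
}
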