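# Validation report: per-score ROC/AUC with CI and Youden-cutoff metrics,
# plus paired comparisons (DeLong on AUC; McNemar on sensitivity, specificity
# and CC; Wald on PPV/NPV) for requested score pairs. Mirrors the structure
# of an ROC-overlay figure, a metric bar chart and a probability curve.

#' Full validation report for a table of scores
#'
#' @param scores data.frame with `patient_id` and one numeric column per
#'   score.
#' @param outcomes data.frame from [outcome_records()]; matched to `scores`
#'   by `patient_id` (unmatched ids are an error).
#' @param compare list of length-2 character vectors (or "a:b" strings)
#'   naming score pairs to compare.
#' @param alpha significance level for single comparisons.
#' @param alpha_multi significance level for the multiple-comparison family.
#' @param window optional window tag carried into the report.
#' @return An `incns_report` list: `cohort` (from [cohort_summary()]),
#'   `scores` (per score: `auc`, `ci95`, Youden-cutoff metrics) and
#'   `comparisons` (per pair: AUC, sensitivity, specificity, PPV, NPV, CC
#'   statistics, p-values and significance flags at `alpha_multi`).
#' @export
validation_report <- function(scores, outcomes, compare = list(),
                              alpha = 0.05, alpha_multi = 0.0167,
                              window = NA) {
  stopifnot("patient_id" %in% names(scores))
  score_names <- setdiff(names(scores), "patient_id")
  if (length(score_names) == 0L) stop("no score columns", call. = FALSE)
  m <- match(scores$patient_id, outcomes$patient_id)
  if (anyNA(m))
    stop("unmatched patient id(s) in scores: ",
         paste(utils::head(scores$patient_id[is.na(m)], 5), collapse = ", "),
         call. = FALSE)
  labels <- outcomes$unfavorable[m]

  per_score <- list()
  preds <- list()
  for (nm in score_names) {
    r <- roc(scores[[nm]], labels, name = nm, window = window)
    cm <- youden_cutoff(r)
    preds[[nm]] <- scores[[nm]] >= cm$cutoff
    per_score[[nm]] <- list(
      auc = r$auc, ci95 = r$ci95, cutoff = cm$cutoff,
      sensitivity = cm$sensitivity, specificity = cm$specificity,
      ppv = cm$ppv, npv = cm$npv, cc = cm$cc,
      counts = as.list(cm$counts), roc = r)
  }

  compare <- lapply(compare, function(p)
    if (is.character(p) && length(p) == 1L) strsplit(p, ":", fixed = TRUE)[[1]]
    else p)
  comparisons <- list()
  for (p in compare) {
    if (length(p) != 2L || !all(p %in% score_names))
      stop("comparison pair must name two score columns: ",
           paste(p, collapse = ":"), call. = FALSE)
    a <- p[1]; b <- p[2]
    d <- auc_ci_and_compare(scores[[a]], scores[[b]], labels)
    pa <- preds[[a]]; pb <- preds[[b]]
    sens <- mcnemar_paired((pa == labels)[labels], (pb == labels)[labels])
    spec <- mcnemar_paired((pa == labels)[!labels], (pb == labels)[!labels])
    cc <- mcnemar_paired(pa == labels, pb == labels)
    pv <- compare_predictive_values(pa, pb, labels)
    res <- list(
      pair = paste(a, b, sep = ":"),
      auc = list(delta = d$delta, z = d$z, p = d$p),
      sensitivity = list(statistic = sens$statistic, p = sens$p),
      specificity = list(statistic = spec$statistic, p = spec$p),
      cc = list(statistic = cc$statistic, p = cc$p),
      ppv = list(estimate = pv$rppv, statistic = pv$stat_ppv, p = pv$p_ppv),
      npv = list(estimate = pv$rnpv, statistic = pv$stat_npv, p = pv$p_npv))
    for (metric in c("auc", "sensitivity", "specificity", "cc", "ppv", "npv"))
      res[[metric]]$significant <- res[[metric]]$p < alpha_multi
    comparisons[[paste(a, b, sep = ":")]] <- res
  }

  structure(list(window = window, alpha = alpha, alpha_multi = alpha_multi,
                 cohort = cohort_summary(outcomes), scores = per_score,
                 comparisons = comparisons),
            class = "incns_report")
}

#' @export
print.incns_report <- function(x, ...) {
  cat("Validation report",
      if (!is.na(x$window)) sprintf("(%s h window)", x$window), "\n")
  cat(sprintf("  cohort: n=%d, unfavorable %.1f%%, died %.1f%%\n",
              x$cohort$n, x$cohort$pct_unfavorable, x$cohort$pct_died))
  for (nm in names(x$scores)) {
    s <- x$scores[[nm]]
    cat(sprintf("  %-9s AUC %.3f (%.3f-%.3f) cutoff>=%s sens %.3f spec %.3f CC %.3f\n",
                nm, s$auc, s$ci95[1], s$ci95[2], format(s$cutoff),
                s$sensitivity, s$specificity, s$cc))
  }
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    cat(sprintf("  %s: dAUC %+0.3f (p=%.4g)%s\n", nm, cmp$auc$delta,
                cmp$auc$p, if (cmp$auc$significant) " *" else ""))
  }
  invisible(x)
}

# strip non-serializable members for the JSON report
report_to_json_list <- function(report) {
  out <- unclass(report)
  out$scores <- lapply(out$scores, function(s) { s$roc <- NULL; s })
  out
}

#' Write a validation report as JSON
#'
#' @param report an `incns_report` from [validation_report()].
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_json_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Overlay ROC curves of several scores
#'
#' @param rocs list of `incns_roc` objects.
#' @param main plot title.
#' @export
plot_roc_overlay <- function(rocs, main = "ROC comparison") {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "1 - specificity", ylab = "sensitivity", main = main)
  cols <- seq_along(rocs) + 1L
  for (i in seq_along(rocs))
    graphics::lines(rocs[[i]]$curve$fpr, rocs[[i]]$curve$tpr, col = cols[i])
  graphics::legend("bottomright", bty = "n", col = cols, lty = 1,
                   legend = vapply(rocs, function(r)
                     sprintf("%s (AUC %.3f)", r$name, r$auc), character(1)))
  invisible(NULL)
}

#' Plot the logistic score-to-probability curve
#'
#' @param fit result of [fit_outcome_probability()].
#' @export
plot_probability_curve <- function(fit) {
  graphics::plot(fit$curve$score, fit$curve$probability, type = "l",
                 xlab = "score", ylab = "P(unfavorable outcome)",
                 ylim = c(0, 1), main = "Score-to-probability map")
  invisible(NULL)
}
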