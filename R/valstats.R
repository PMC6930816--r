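# Validation battery: empirical ROC/AUC (Mann-Whitney, mid-rank ties),
# DeLong variance and paired AUC comparison, Youden cutoff with confusion
# metrics, paired McNemar tests, Wald comparison of predictive values on the
# paired multinomial cells, and the logistic score-to-probability map.
# Single comparisons are judged at alpha = 0.05; families of score-vs-score
# performance comparisons at alpha = 0.0167.

alpha_single <- 0.05
alpha_multiple <- 0.0167

check_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels))
    stop("scores/labels contain missing values", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("labels must contain both classes", call. = FALSE)
  labels
}

#' Outcome records from 3-month mRS
#'
#' Dichotomizes the modified Rankin Scale at 3: mRS < 3 is favorable
#' (independence), mRS >= 3 unfavorable (dependence or death).
#'
#' @param patient_id vector of patient identifiers.
#' @param mrs_3month integer mRS grades, 0-6.
#' @return data.frame with `patient_id`, `mrs_3month`, `unfavorable`.
#' @export
outcome_records <- function(patient_id, mrs_3month) {
  if (any(!is.finite(mrs_3month)) || any(mrs_3month != round(mrs_3month)) ||
      any(mrs_3month < 0) || any(mrs_3month > 6))
    stop("mrs_3month must be integers in [0, 6]", call. = FALSE)
  if (length(patient_id) != length(mrs_3month))
    stop("patient_id and mrs_3month differ in length", call. = FALSE)
  data.frame(patient_id = patient_id, mrs_3month = as.integer(mrs_3month),
             unfavorable = mrs_3month >= 3, stringsAsFactors = FALSE)
}

#' Cohort outcome summary
#'
#' Counts and percentages (to one decimal, as conventionally reported) of
#' favorable (mRS 0-2), unfavorable (mRS 3-6) and dead (mRS 6) patients.
#'
#' @param outcomes data.frame from [outcome_records()].
#' @return list with `n`, counts and `pct_*` percentages on the 0-100 scale.
#' @export
cohort_summary <- function(outcomes) {
  stopifnot(all(c("mrs_3month") %in% names(outcomes)))
  n <- nrow(outcomes)
  fav <- sum(outcomes$mrs_3month < 3)
  unfav <- sum(outcomes$mrs_3month >= 3)
  died <- sum(outcomes$mrs_3month == 6)
  pct <- function(k) round(100 * k / n, 1)
  list(n = n, n_favorable = fav, n_unfavorable = unfav, n_died = died,
       pct_favorable = pct(fav), pct_unfavorable = pct(unfav),
       pct_died = pct(died))
}

# 95% CI for an AUC: normal approximation on the logit scale (delta method
# on the DeLong standard error), which respects the [0,1] bounds and is
# better calibrated near high AUCs than the untransformed interval.
# Degenerate cases (AUC 0 or 1, zero variance) collapse to a point.
auc_ci_logit <- function(auc, se, level = 0.95) {
  if (se == 0 || auc <= 0 || auc >= 1) return(c(auc, auc))
  q <- stats::qnorm(1 - (1 - level) / 2)
  lse <- se / (auc * (1 - auc))
  c(stats::plogis(stats::qlogis(auc) - q * lse),
    stats::plogis(stats::qlogis(auc) + q * lse))
}

# DeLong placement values. v10: per-positive, v01: per-negative.
delong_placements <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  m <- length(pos); n <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r[seq_len(m)] - rank(pos, ties.method = "average")) / n
  v01 <- 1 - (r[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' Empirical ROC curve and AUC
#'
#' Computes the empirical ROC over all distinct thresholds with the
#' classification rule "score >= threshold predicts unfavorable", the AUC by
#' the mid-rank Mann-Whitney statistic (equal to the trapezoidal area under
#' the tie-merged curve), and a 95% confidence interval from the DeLong
#' standard error (normal approximation on the logit scale).
#'
#' @param scores numeric severity scores (higher = more severe).
#' @param labels logical (or 0/1) outcome labels, `TRUE` = unfavorable.
#' @param name optional score name carried into reports.
#' @param window optional window tag (e.g. 24 or 72) carried into reports.
#' @return An `incns_roc`: list with `auc`, `ci95`, `curve` (data.frame of
#'   `fpr`, `tpr`, `threshold`), the inputs, and class counts.
#' @export
#' @examples
#' r <- roc(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE))
#' r$auc # 0.75
roc <- function(scores, labels, name = "score", window = NA) {
  labels <- check_labels(scores, labels)
  pl <- delong_placements(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE) # last row of each distinct score
  tpr <- cumsum(l)[last] / pl$m
  fpr <- cumsum(!l)[last] / pl$n
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                      threshold = c(Inf, s[last]))
  se <- sqrt(stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n)
  ci <- auc_ci_logit(pl$auc, se)
  structure(list(name = name, window = window, auc = pl$auc, se = se,
                 ci95 = ci, curve = curve, scores = scores, labels = labels,
                 n_pos = pl$m, n_neg = pl$n),
            class = "incns_roc")
}

#' @export
print.incns_roc <- function(x, ...) {
  cat(sprintf("ROC for %s%s: AUC %.3f (95%% CI %.3f-%.3f), %d+/%d- patients\n",
              x$name, if (is.na(x$window)) "" else paste0(" @", x$window, "h"),
              x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong confidence intervals and paired AUC comparison
#'
#' Estimates each score's AUC variance with the DeLong placement-value
#' estimator, forms 95% logit-scale normal-approximation confidence
#' intervals, and tests
#' the paired difference in AUC with a two-sided z-test using the DeLong
#' covariance (both scores on the same patients).
#'
#' @param scores_a,scores_b paired numeric scores on the same patients.
#' @param labels logical outcome labels.
#' @return list with `auc_a`, `auc_b`, `ci_a`, `ci_b`, `delta` (a - b),
#'   `se_delta`, `z`, `p`.
#' @export
auc_ci_and_compare <- function(scores_a, scores_b, labels) {
  labels <- check_labels(scores_a, labels)
  check_labels(scores_b, labels)
  if (stats::var(scores_a) == 0 || stats::var(scores_b) == 0)
    stop("degenerate input: a score is constant, AUC variance undefined",
         call. = FALSE)
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  va <- stats::var(pa$v10) / pa$m + stats::var(pa$v01) / pa$n
  vb <- stats::var(pb$v10) / pb$m + stats::var(pb$v01) / pb$n
  cab <- stats::cov(pa$v10, pb$v10) / pa$m + stats::cov(pa$v01, pb$v01) / pa$n
  ci <- function(auc, v) auc_ci_logit(auc, sqrt(v))
  delta <- pa$auc - pb$auc
  se_d <- sqrt(max(0, va + vb - 2 * cab))
  if (se_d == 0) {
    z <- 0; p <- 1
    if (delta != 0)
      stop("degenerate paired variance with nonzero AUC difference",
           call. = FALSE)
  } else {
    z <- delta / se_d
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, ci_a = ci(pa$auc, va),
       ci_b = ci(pb$auc, vb), delta = delta, se_delta = se_d, z = z, p = p)
}

#' Youden-index cutoff and confusion metrics
#'
#' Selects the cutoff maximizing sensitivity + specificity - 1 over all
#' distinct thresholds of an [roc()] result (smallest cutoff on ties) and
#' returns the full confusion metrics at that cutoff under the rule
#' "score >= cutoff predicts unfavorable".
#'
#' @param roc_result an `incns_roc` from [roc()].
#' @return A `cutoff_metrics`: list with `cutoff`, `youden`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `cc` (proportion correctly classified) and
#'   integer `counts` (tp, fp, tn, fn).
#' @export
youden_cutoff <- function(roc_result) {
  stopifnot(inherits(roc_result, "incns_roc"))
  s <- roc_result$scores
  l <- roc_result$labels
  m <- roc_result$n_pos
  n <- roc_result$n_neg
  ord <- order(s, decreasing = TRUE)
  ss <- s[ord]; ll <- l[ord]
  last <- !duplicated(ss, fromLast = TRUE)
  cand <- c(Inf, ss[last])
  tp <- c(0, cumsum(ll)[last])
  fp <- c(0, cumsum(!ll)[last])
  # maximize J = tp/m - fp/n via the integer score tp*n - fp*m (tie-exact)
  jint <- tp * n - fp * m
  best <- which(jint == max(jint))
  cut <- min(cand[best])
  cutoff_metrics(s, l, cut)
}

#' Confusion metrics at a fixed cutoff
#'
#' @param scores numeric scores.
#' @param labels logical outcome labels.
#' @param cutoff classification cutoff; `score >= cutoff` predicts
#'   unfavorable.
#' @return A `cutoff_metrics` (see [youden_cutoff()]).
#' @export
cutoff_metrics <- function(scores, labels, cutoff) {
  labels <- check_labels(scores, labels)
  pred <- scores >= cutoff
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  structure(list(cutoff = cutoff, youden = sens + spec - 1,
                 sensitivity = sens, specificity = spec,
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NaN,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NaN,
                 cc = (tp + tn) / length(labels),
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "cutoff_metrics")
}

#' @export
print.cutoff_metrics <- function(x, ...) {
  cat(sprintf(paste0("cutoff >= %s: sens %.3f, spec %.3f, PPV %.3f, ",
                     "NPV %.3f, CC %.3f (Youden %.3f)\n"),
              format(x$cutoff), x$sensitivity, x$specificity, x$ppv, x$npv,
              x$cc, x$youden))
  invisible(x)
}

#' Paired McNemar test
#'
#' Compares two paired classifiers through their discordant counts
#' `b = sum(a correct, b wrong)` and `c = sum(a wrong, b correct)`. The
#' statistic is the continuity-corrected chi-square `(|b - c| - 1)^2 /
#' (b + c)`. The p-value uses that chi-square when `b + c >= 25` and the
#' exact two-sided binomial test otherwise; `b + c = 0` returns p = 1 by
#' convention.
#'
#' To compare sensitivities, restrict the correctness vectors to truly
#' unfavorable patients; specificities to truly favorable patients; CC uses
#' all patients.
#'
#' @param a_correct,b_correct paired logical vectors: was each classifier
#'   correct on each patient.
#' @return list with `b`, `c`, `statistic`, `p`, `method`.
#' @export
#' @examples
#' # b = 5, c = 15: statistic (|5-15|-1)^2/20 = 4.05
#' mcnemar_paired(rep(c(TRUE, FALSE), c(5, 15)),
#'                rep(c(FALSE, TRUE), c(5, 15)))$statistic
mcnemar_paired <- function(a_correct, b_correct) {
  stopifnot(length(a_correct) == length(b_correct))
  a <- as.logical(a_correct); b <- as.logical(b_correct)
  if (anyNA(a) || anyNA(b)) stop("missing values in correctness vectors",
                                 call. = FALSE)
  nb <- sum(a & !b); nc <- sum(!a & b)
  nd <- nb + nc
  if (nd == 0)
    return(list(b = nb, c = nc, statistic = 0, p = 1, method = "no discordant pairs"))
  stat <- (abs(nb - nc) - 1)^2 / nd
  if (nd >= 25) {
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "continuity-corrected chi-square"
  } else {
    p <- min(1, 2 * stats::pbinom(min(nb, nc), nd, 0.5))
    method <- "exact binomial"
  }
  list(b = nb, c = nc, statistic = stat, p = p, method = method)
}

# Paired multinomial cell probabilities over (pred_a, pred_b, label)
paired_cells <- function(pred_a, pred_b, labels) {
  idx <- 1L + pred_a + 2L * pred_b + 4L * labels
  counts <- tabulate(idx, nbins = 8L)
  array(counts, dim = c(2, 2, 2),
        dimnames = list(a = c("0", "1"), b = c("0", "1"), d = c("0", "1")))
}

# Wald test on a log relative proportion of the form
# log(s_a/t_a) - log(s_b/t_b), with s/t linear in the 8 paired multinomial
# cells. `sel` returns the (s, t) selector masks for one classifier.
log_rpv_test <- function(cells, sel_a, sel_b) {
  n <- sum(cells)
  counts <- as.vector(cells)
  sa <- sum(counts[sel_a$s]); ta <- sum(counts[sel_a$t])
  sb <- sum(counts[sel_b$s]); tb <- sum(counts[sel_b$t])
  if (ta == 0 || tb == 0)
    stop("a classifier makes no predictions in the required class; ",
         "predictive value undefined", call. = FALSE)
  if (sa == 0 || sb == 0 || sa == ta || sb == tb) {
    counts <- counts + 0.5
    sa <- sum(counts[sel_a$s]); ta <- sum(counts[sel_a$t])
    sb <- sum(counts[sel_b$s]); tb <- sum(counts[sel_b$t])
    n <- sum(counts)
  }
  g <- log(sa / ta) - log(sb / tb)
  p_hat <- counts / n
  grad <- (sel_a$s / sa - sel_a$t / ta) - (sel_b$s / sb - sel_b$t / tb)
  grad <- grad * n # derivatives w.r.t. cell probabilities
  v <- (sum(p_hat * grad^2) - sum(p_hat * grad)^2) / n
  if (v <= 0) return(list(estimate = exp(g), statistic = 0, p = 1))
  z <- g / sqrt(v)
  list(estimate = exp(g), statistic = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare positive and negative predictive values of paired classifiers
#'
#' Wald-type tests on the log relative predictive values, with variance from
#' the paired multinomial cell counts over (prediction A, prediction B,
#' outcome). Identical prediction vectors return p = 1 for both tests.
#'
#' @param pred_a,pred_b paired logical predictions (`TRUE` = predicted
#'   unfavorable).
#' @param labels logical outcome labels.
#' @return list with `rppv`, `stat_ppv`, `p_ppv`, `rnpv`, `stat_npv`,
#'   `p_npv`.
#' @export
compare_predictive_values <- function(pred_a, pred_b, labels) {
  stopifnot(length(pred_a) == length(labels), length(pred_b) == length(labels))
  pred_a <- as.logical(pred_a); pred_b <- as.logical(pred_b)
  labels <- as.logical(labels)
  if (!any(pred_a) || !any(pred_b))
    stop("a classifier predicts no positives; PPV undefined", call. = FALSE)
  if (all(pred_a) || all(pred_b))
    stop("a classifier predicts no negatives; NPV undefined", call. = FALSE)
  if (identical(pred_a, pred_b))
    return(list(rppv = 1, stat_ppv = 0, p_ppv = 1,
                rnpv = 1, stat_npv = 0, p_npv = 1))
  cells <- paired_cells(pred_a, pred_b, labels)
  # cell index layout: 1 + a + 2b + 4d
  a1 <- rep(c(FALSE, TRUE), 4)           # a == 1
  b1 <- rep(rep(c(FALSE, TRUE), each = 2), 2) # b == 1
  d1 <- rep(c(FALSE, TRUE), each = 4)    # d == 1
  ppv <- log_rpv_test(cells,
                      sel_a = list(s = a1 & d1, t = a1),
                      sel_b = list(s = b1 & d1, t = b1))
  npv <- log_rpv_test(cells,
                      sel_a = list(s = !a1 & !d1, t = !a1),
                      sel_b = list(s = !b1 & !d1, t = !b1))
  list(rppv = ppv$estimate, stat_ppv = ppv$statistic, p_ppv = ppv$p,
       rnpv = npv$estimate, stat_npv = npv$statistic, p_npv = npv$p)
}

#' Logistic score-to-probability map
#'
#' Fits a univariate logistic regression of the binary unfavorable outcome on
#' the integer score and returns the predicted probability of an unfavorable
#' outcome at every score value. Under complete (or quasi-complete)
#' separation, the maximum-likelihood fit diverges; the function then falls
#' back to Firth's bias-reduced logistic regression and flags it.
#'
#' @param scores numeric (typically integer) scores.
#' @param labels logical outcome labels.
#' @param score_grid score values at which to evaluate the curve
#'   (default 0-44).
#' @return list with `intercept`, `slope`, `curve` (data.frame `score`,
#'   `probability`), `method` ("mle" or "firth"), `separation` flag.
#' @export
fit_outcome_probability <- function(scores, labels, score_grid = 0:44) {
  labels <- check_labels(scores, labels)
  y <- as.numeric(labels)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ scores, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (separation || !fit$converged || any(abs(cf) > 50)) {
    separation <- TRUE
    cf <- firth_logistic(cbind(1, scores), y)
    method <- "firth"
  } else method <- "mle"
  prob <- stats::plogis(cf[1] + cf[2] * score_grid)
  list(intercept = unname(cf[1]), slope = unname(cf[2]),
       curve = data.frame(score = score_grid, probability = prob),
       method = method, separation = separation)
}

# Firth bias-reduced logistic regression (Jeffreys-prior score adjustment),
# Newton iterations; enough for the univariate fallback.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * w
    XtWX <- crossprod(X, XW)
    h <- rowSums((X %*% solve(XtWX)) * X) * w # hat-matrix diagonal
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- solve(XtWX, U)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}
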