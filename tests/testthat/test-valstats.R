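test_that("ROC handles the canonical examples", {
  # perfect separation
  r <- roc(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_identical(r$auc, 1)
  # worked examples
  expect_identical(roc(c(1, 2, 3, 4), c(F, F, T, T))$auc, 1)
  expect_identical(roc(c(1, 3, 2, 4), c(F, F, T, T))$auc, 0.75)
  # chance level at large n
  set.seed(1)
  s <- rnorm(4000); l <- runif(4000) < 0.5
  expect_lt(abs(roc(s, l)$auc - 0.5), 0.03)
  # degenerate labels rejected
  expect_error(roc(1:4, c(TRUE, TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC equals the pairwise win-fraction oracle (with ties)", {
  set.seed(2)
  for (i in 1:25) {
    fx <- random_fixture(sample(2:200, 1))
    r <- roc(fx$scores, fx$labels)
    expect_equal(r$auc, oracle_auc(fx$scores, fx$labels), tolerance = 1e-12)
    expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
    # curve is monotone nondecreasing in both coordinates
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
  }
})

test_that("paired AUC comparison: identity, symmetry, degeneracy", {
  set.seed(3)
  fx <- random_fixture(80)
  b <- fx$scores + sample(-2:2, 80, replace = TRUE)
  same <- auc_ci_and_compare(fx$scores, fx$scores, fx$labels)
  expect_identical(same$p, 1)
  expect_identical(same$delta, 0)
  ab <- auc_ci_and_compare(fx$scores, b, fx$labels)
  ba <- auc_ci_and_compare(b, fx$scores, fx$labels)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$delta, -ba$delta)
  expect_error(auc_ci_and_compare(rep(1, 80), b, fx$labels), "degenerate")
})

test_that("DeLong variance matches a 10,000-rep bootstrap on a small fixture", {
  s <- c(2, 5, 3, 8, 6, 4, 9, 7, 10, 1)
  l <- c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  r <- roc(s, l)
  set.seed(99)
  boot <- replicate(10000, {
    i <- sample(10, replace = TRUE)
    if (any(l[i]) && !all(l[i])) oracle_auc(s[i], l[i]) else NA
  })
  expect_lt(abs(stats::var(boot, na.rm = TRUE) / r$se^2 - 1), 0.10)
})

test_that("Youden cutoff matches exhaustive search and its own counts", {
  set.seed(4)
  for (i in 1:20) {
    fx <- random_fixture(sample(10:150, 1))
    cm <- youden_cutoff(roc(fx$scores, fx$labels))
    or <- oracle_youden(fx$scores, fx$labels)
    expect_equal(cm$cutoff, or$cutoff)
    expect_equal(cm$youden, or$youden, tolerance = 1e-12)
    # internal consistency with the confusion counts
    ct <- cm$counts
    expect_equal(cm$sensitivity, ct[["tp"]] / (ct[["tp"]] + ct[["fn"]]))
    expect_equal(cm$specificity, ct[["tn"]] / (ct[["tn"]] + ct[["fp"]]))
    expect_equal(cm$cc, (ct[["tp"]] + ct[["tn"]]) / sum(ct))
  }
  # perfect separator: Youden 1, smallest qualifying cutoff returned
  cm <- youden_cutoff(roc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)))
  expect_identical(cm$youden, 1)
  expect_identical(cm$cutoff, 10)
  # random labels: Youden near zero on average
  set.seed(5)
  js <- replicate(40, {
    fx <- random_fixture(400)
    youden_cutoff(roc(fx$scores, fx$labels))$youden
  })
  expect_lt(mean(js), 0.15)
})

test_that("McNemar test: worked example, conventions, exact-binomial switch", {
  ex <- mcnemar_paired(rep(c(TRUE, FALSE), c(5, 15)),
                       rep(c(FALSE, TRUE), c(5, 15)))
  expect_equal(ex$statistic, (abs(5 - 15) - 1)^2 / 20)
  expect_equal(ex$statistic, 4.05)
  # b + c = 20 < 25: exact binomial p
  expect_equal(ex$p, min(1, 2 * pbinom(5, 20, 0.5)))
  expect_match(ex$method, "binomial")
  # large discordance uses the chi-square
  big <- mcnemar_paired(rep(c(TRUE, FALSE), c(20, 20)),
                        rep(c(FALSE, TRUE), c(20, 20)))
  expect_match(big$method, "chi-square")
  expect_equal(big$p, pchisq(big$statistic, 1, lower.tail = FALSE))
  # identical classifications
  x <- c(TRUE, FALSE, TRUE)
  expect_identical(mcnemar_paired(x, x)$p, 1)
  # symmetry
  set.seed(6)
  a <- runif(60) < 0.7; b <- runif(60) < 0.7
  expect_equal(mcnemar_paired(a, b)$p, mcnemar_paired(b, a)$p)
})

test_that("predictive-value comparison: identity, symmetry, rejections", {
  set.seed(7)
  d <- runif(200) < 0.6
  a <- xor(d, runif(200) < 0.2)
  b <- xor(d, runif(200) < 0.2)
  same <- compare_predictive_values(a, a, d)
  expect_identical(same$p_ppv, 1)
  expect_identical(same$p_npv, 1)
  ab <- compare_predictive_values(a, b, d)
  ba <- compare_predictive_values(b, a, d)
  expect_equal(ab$p_ppv, ba$p_ppv)
  expect_equal(ab$p_npv, ba$p_npv)
  expect_equal(ab$rppv, 1 / ba$rppv, tolerance = 1e-12)
  expect_true(all(c(ab$p_ppv, ab$p_npv) >= 0 & c(ab$p_ppv, ab$p_npv) <= 1))
  expect_error(compare_predictive_values(rep(FALSE, 200), b, d),
               "no positives")
  expect_error(compare_predictive_values(rep(TRUE, 200), b, d),
               "no negatives")
})

test_that("predictive-value Wald statistic tracks a paired bootstrap", {
  set.seed(8)
  n <- 300
  d <- runif(n) < 0.6
  a <- xor(d, runif(n) < 0.15)
  b <- xor(d, runif(n) < 0.3)
  res <- compare_predictive_values(a, b, d)
  boot <- replicate(2000, {
    i <- sample(n, replace = TRUE)
    ppv_a <- mean(d[i][a[i]]); ppv_b <- mean(d[i][b[i]])
    log(ppv_a / ppv_b)
  })
  # analytic SE of log rPPV within 15% of the bootstrap SE
  se_analytic <- log(res$rppv) / res$stat_ppv
  expect_lt(abs(se_analytic / stats::sd(boot) - 1), 0.15)
})

test_that("logistic probability map recovers parameters and is monotone", {
  set.seed(9)
  s <- sample(0:44, 2000, replace = TRUE)
  p <- plogis(-4 + 0.3 * s)
  y <- runif(2000) < p
  fit <- fit_outcome_probability(s, y)
  expect_identical(fit$method, "mle")
  expect_lt(abs(fit$slope - 0.3), 0.05)
  expect_true(all(diff(fit$curve$probability) > 0))
  expect_identical(nrow(fit$curve), 45L)

  # slope-zero truth: curve stays near prevalence
  y0 <- runif(2000) < 0.4
  fit0 <- fit_outcome_probability(s, y0)
  expect_true(all(abs(fit0$curve$probability - 0.4) < 0.1))

  # complete separation falls back to the bias-reduced fit
  ssep <- c(0:9, 20:29)
  ysep <- rep(c(FALSE, TRUE), each = 10)
  fit_sep <- fit_outcome_probability(ssep, ysep)
  expect_true(fit_sep$separation)
  expect_identical(fit_sep$method, "firth")
  expect_true(is.finite(fit_sep$slope) && fit_sep$slope > 0)
})

test_that("cohort_summary reproduces printed proportions", {
  out <- outcome_records(1:10, c(0, 1, 2, 2, 3, 4, 5, 6, 6, 6))
  cs <- cohort_summary(out)
  expect_identical(cs$n, 10L)
  expect_identical(cs$n_favorable, 4L)
  expect_identical(cs$pct_unfavorable, 60)
  expect_identical(cs$pct_died, 30)
  expect_identical(out$unfavorable, out$mrs_3month >= 3)
  expect_error(outcome_records(1:2, c(3, 7)), "0, 6")
})

test_that("validation_report assembles metrics and comparisons", {
  set.seed(10)
  n <- 150
  z <- rnorm(n)
  out <- outcome_records(sprintf("P%03d", 1:n),
                         ifelse(plogis(0.4 + 1.5 * z) > runif(n), 4, 1))
  # guarantee both classes
  out$mrs_3month[1:2] <- c(1L, 4L)
  out$unfavorable <- out$mrs_3month >= 3
  scores <- data.frame(patient_id = out$patient_id,
                       good = round(10 + 8 * z + rnorm(n)),
                       noisy = round(10 + 2 * z + 4 * rnorm(n)))
  rep <- validation_report(scores, out,
                           compare = list(c("good", "noisy"), "good:good"))
  expect_named(rep$scores, c("good", "noisy"))
  expect_gt(rep$scores$good$auc, rep$scores$noisy$auc)
  expect_identical(rep$comparisons$`good:good`$auc$p, 1)
  expect_identical(rep$comparisons$`good:good`$cc$p, 1)
  expect_true(rep$comparisons$`good:noisy`$auc$p >= 0 &&
                rep$comparisons$`good:noisy`$auc$p <= 1)
  expect_identical(rep$alpha_multi, 0.0167)
  # unmatched ids rejected
  bad <- scores; bad$patient_id[1] <- "missing"
  expect_error(validation_report(bad, out), "unmatched")
})
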