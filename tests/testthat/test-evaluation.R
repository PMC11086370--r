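trap_area <- function(cur) {
  sum(diff(cur$fpr) * (head(cur$tpr, -1) + cur$tpr[-1]) / 2)
}

test_that("AUC equals the Mann-Whitney pair statistic", {
  expect_equal(auc(c(4, 5, 6, 1, 2, 3), c(1, 1, 1, 0, 0, 0)), 1)
  expect_equal(auc(c(1, 2, 1, 2), c(1, 1, 0, 0)), 0.5)
  expect_equal(auc(c(3, 1, 2, 0), c(1, 1, 0, 0)), 0.75)
  set.seed(3)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) < 2) next
    sc <- round(rnorm(n), sample(0:2, 1)) # rounding induces ties
    expect_equal(auc(sc, lab), brute_auc(sc, lab), tolerance = 1e-12)
    expect_equal(auc(sc, lab) + auc(-sc, lab), 1, tolerance = 1e-12)
  }
  expect_error(auc(1:4, rep(1, 4)), class = "imsvoc_input_error")
})

test_that("the ROC curve is monotone from (0,0) to (1,1) and its trapezoid area is the pair-count AUC", {
  sc <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  lab <- c(1, 1, 1, 0, 0, 0)
  cur <- roc_curve(sc, lab)
  expect_equal(cur$fpr[1], 0)
  expect_equal(cur$tpr[1], 0)
  expect_equal(cur$fpr[nrow(cur)], 1)
  expect_equal(cur$tpr[nrow(cur)], 1)
  expect_true(!is.unsorted(cur$fpr) && !is.unsorted(cur$tpr))

  perfect <- roc_curve(c(2, 3, 0, 1), c(1, 1, 0, 0))
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))

  flat <- roc_curve(rep(1, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(nrow(flat), 2)
  expect_equal(trap_area(flat), 0.5)

  set.seed(17)
  for (i in 1:10) {
    n <- sample(20:100, 1)
    lab <- c(0, 1, rbinom(n - 2, 1, 0.4))
    sc <- round(runif(n), 2)
    cur <- roc_curve(sc, lab)
    expect_equal(trap_area(cur), brute_auc(sc, lab), tolerance = 1e-12)
  }
})

test_that("AUC and DeLong intervals agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:5) {
    lab <- rep(c(0, 1), times = c(40, 50))
    sc <- rnorm(90) + lab
    ref <- pROC::roc(lab, sc, quiet = TRUE, direction = "<")
    expect_equal(auc(sc, lab), as.numeric(pROC::auc(ref)),
                 tolerance = 1e-12)
    ci <- pROC::ci.auc(ref, method = "delong")
    expect_equal(auc_ci(sc, lab, method = "delong"),
                 as.numeric(ci[c(1, 3)]), tolerance = 1e-9)
  }
})

test_that("Hanley-McNeil closed form reproduces its degenerate and published values", {
  expect_equal(hanley_mcneil_se(1, 30, 20), 0)
  expect_equal(auc_ci(c(10, 11, 12, 1, 2, 3), c(1, 1, 1, 0, 0, 0),
                      method = "hanley_mcneil"), c(1, 1))
  # direct evaluation of the closed form at the design point
  a <- 0.87
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + 122 * (q1 - a^2) + 61 * (q2 - a^2)) / (123 * 62))
  expect_equal(hanley_mcneil_se(0.87, 123, 62), se, tolerance = 1e-14)
  expect_equal(ci_width_for_design(0.87, 123, 62), 2 * qnorm(0.975) * se,
               tolerance = 1e-14)
  expect_equal(ci_width_for_design(0.87, 123, 62), 0.0995, tolerance = 1e-3)
})

test_that("design width shrinks with n, vanishes as AUC approaches 1, and rejects out-of-domain AUCs", {
  w1 <- ci_width_for_design(0.8, 60, 40)
  w2 <- ci_width_for_design(0.8, 120, 80)
  expect_equal(w2 / w1, 1 / sqrt(2), tolerance = 0.05)
  # strict monotonicity in each group size
  expect_true(all(diff(sapply(seq(30, 300, 30),
                              function(n) ci_width_for_design(0.8, n, 50))) < 0))
  expect_true(all(diff(sapply(seq(30, 300, 30),
                              function(n) ci_width_for_design(0.8, 50, n))) < 0))
  expect_lt(ci_width_for_design(0.9999, 100, 100), 1e-2)
  expect_lt(ci_width_for_design(0.9999, 100, 100),
            ci_width_for_design(0.99, 100, 100))
  expect_error(ci_width_for_design(0.3, 50, 50), class = "imsvoc_domain_error")
  expect_error(ci_width_for_design(1, 50, 50), class = "imsvoc_domain_error")
})

test_that("DeLong and Hanley-McNeil intervals agree within 20% relative width at moderate AUCs", {
  set.seed(41)
  for (mu in c(0.4, 0.9, 1.6)) { # AUCs roughly 0.61, 0.74, 0.87
    lab <- rep(c(0, 1), each = 60)
    sc <- rnorm(120) + mu * lab
    wd <- diff(auc_ci(sc, lab, method = "delong"))
    wh <- diff(auc_ci(sc, lab, method = "hanley_mcneil"))
    expect_lt(abs(wd - wh) / wh, 0.2)
  }
})

test_that("DeLong intervals cover the generating AUC at close to the nominal rate", {
  mu <- 1 # binormal separation; true AUC = pnorm(1/sqrt(2))
  true_auc <- pnorm(mu / sqrt(2))
  set.seed(73)
  hits <- vapply(seq_len(1000), function(i) {
    lab <- rep(c(0, 1), each = 40)
    sc <- rnorm(80) + mu * lab
    ci <- auc_ci(sc, lab, method = "delong")
    ci[1] <= true_auc && true_auc <= ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.91)
  expect_lt(mean(hits), 0.98)
})

test_that("the AUC p-value is the rank-sum test of the class score distributions", {
  expect_equal(auc_pvalue(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1 / 3)
  sc <- c(rnorm(10), rnorm(12))
  lab <- rep(c(0, 1), times = c(10, 12))
  expect_identical(auc_pvalue(sc, lab),
                   rank_sum_pvalue(sc[lab == 1], sc[lab == 0]))
  same <- rep(c(1, 2, 3), 4)
  expect_gt(auc_pvalue(same, rep(c(0, 1), each = 6)), 0.9)
})

test_that("type-I error of the AUC p-value stays near nominal under the null", {
  set.seed(57)
  reject <- vapply(seq_len(500), function(i) {
    sc <- rnorm(100)
    auc_pvalue(sc, rep(c(0, 1), each = 50)) < 0.05
  }, logical(1))
  expect_lte(mean(reject), 0.07)
})

test_that("the optimum cut-off maximises Youden's J with the documented tie-breaks", {
  # exhaustive scan oracle over every candidate cutoff
  scan_best <- function(sc, lab) {
    cand <- c(Inf, sort(unique(sc), decreasing = TRUE))
    stats <- t(vapply(cand, function(ct) {
      sens <- sum(sc >= ct & lab == 1) / sum(lab == 1)
      spec <- sum(sc < ct & lab == 0) / sum(lab == 0)
      c(ct, sens, spec, sens + spec - 1)
    }, numeric(4)))
    top <- which(stats[, 4] >= max(stats[, 4]) - 1e-9)
    stats[top[order(-stats[top, 3], stats[top, 1])][1], ]
  }
  sc <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  lab <- c(1, 1, 1, 0, 0, 0)
  oc <- optimal_cutoff(roc_curve(sc, lab))
  ref <- scan_best(sc, lab)
  expect_equal(oc$cutoff, ref[1])
  expect_equal(oc$sensitivity, ref[2])
  expect_equal(oc$specificity, ref[3])
  expect_equal(oc$youden_j, ref[4])

  set.seed(19)
  for (i in 1:10) {
    sc <- round(runif(30), 1)
    lab <- c(0, 1, rbinom(28, 1, 0.5))
    oc <- optimal_cutoff(roc_curve(sc, lab))
    ref <- scan_best(sc, lab)
    expect_equal(oc$youden_j, ref[4], tolerance = 1e-12)
    expect_equal(oc$cutoff, ref[1])
  }

  perfect <- optimal_cutoff(roc_curve(c(2, 3, 0, 1), c(1, 1, 0, 0)))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  flat <- optimal_cutoff(roc_curve(rep(1, 6), c(1, 1, 1, 0, 0, 0)))
  expect_equal(flat$youden_j, 0)
  expect_equal(flat$sensitivity + flat$specificity, 1)
})

test_that("confusion metrics are the four observed ratios, with NaN for empty denominators", {
  sc <- c(rep(0.9, 59), rep(0.1, 41), rep(0.9, 23), rep(0.1, 77))
  lab <- c(rep(1, 100), rep(0, 100))
  cm <- confusion_metrics(sc, lab, 0.5)
  expect_equal(cm$sensitivity, 59 / 100)
  expect_equal(cm$specificity, 77 / 100)
  expect_equal(cm$ppv, 59 / 82)
  expect_equal(cm$npv, 77 / 118)

  cm2 <- confusion_metrics(c(1, 2, 3, 4), c(0, 0, 1, 1), 0)
  expect_equal(cm2$sensitivity, 1)
  expect_equal(cm2$specificity, 0)
  expect_equal(cm2$ppv, 0.5) # prevalence
  expect_true(is.nan(cm2$npv))

  cm3 <- confusion_metrics(c(5, 6, 1, 2), c(1, 1, 0, 0), 3)
  expect_equal(unlist(cm3[c("sensitivity", "specificity", "ppv", "npv")]),
               c(1, 1, 1, 1), ignore_attr = TRUE)
})

test_that("reports compose the metrics coherently on any score set", {
  set.seed(91)
  for (i in 1:5) {
    sc <- runif(40)
    lab <- c(0, 1, rbinom(38, 1, 0.5))
    rep_ <- build_report(sc, lab)
    expect_lte(rep_$ci_low, rep_$auc)
    expect_gte(rep_$ci_high, rep_$auc)
    expect_gte(rep_$auc, 0)
    expect_lte(rep_$auc, 1)
    expect_true(all(unlist(rep_[c("sensitivity", "specificity")]) >= 0))
    expect_equal(rep_$n_pos + rep_$n_neg, 40)
    cm <- confusion_metrics(sc, lab, rep_$cutoff)
    expect_equal(rep_$sensitivity, cm$sensitivity)
    expect_equal(rep_$ppv, cm$ppv)
  }
  df <- as.data.frame(build_report(runif(20), rep(c(0, 1), 10)))
  expect_equal(nrow(df), 1)
  expect_true(all(c("auc", "ci_low", "ppv", "p_value") %in% names(df)))
})
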