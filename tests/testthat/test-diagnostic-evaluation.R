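test_that("AUC matches hand-checked examples", {
  expect_equal(auc_mann_whitney(1:4, c(FALSE, FALSE, TRUE, TRUE)), 1.0)
  expect_equal(auc_mann_whitney(1:4, c(FALSE, TRUE, FALSE, TRUE)), 0.75)
  expect_equal(auc_mann_whitney(rep(2, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(auc_mann_whitney(1:4, rep(TRUE, 4)), "both classes")
})

test_that("trapezoid, rank-statistic and pair-counting AUC agree to 1e-12", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(4:200, 1)
    pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- if (i %% 2) rnorm(n) else round(rnorm(n), 1)  # with ties
    a_rank <- auc_mann_whitney(scores, pos)
    a_trap <- attr(roc_curve(scores, pos), "auc")
    a_bf <- bf_auc(scores, pos)
    expect_equal(a_rank, a_bf, tolerance = 1e-12)
    expect_equal(a_trap, a_bf, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  for (i in 1:10) {
    scores <- round(rnorm(60), 1)
    pos <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(0.3, 0.7))
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = pos, predictor = scores, levels = c(FALSE, TRUE),
      direction = "<", quiet = TRUE)))
    expect_equal(auc_mann_whitney(scores, pos), ref, tolerance = 1e-12)
  }
})

test_that("orientation flips AUC to its complement", {
  set.seed(2)
  scores <- rnorm(50)
  pos <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  pos[1:2] <- c(TRUE, FALSE)
  a_hi <- auc_mann_whitney(scores, pos, "greater")
  a_lo <- auc_mann_whitney(scores, pos, "less_equal")
  expect_equal(a_hi + a_lo, 1, tolerance = 1e-12)
})

test_that("ROC curves are monotone and pass through the corner points", {
  curve <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(any(curve$sensitivity == 1 & curve$specificity == 1))
  set.seed(4)
  scores <- round(rnorm(40), 1)
  pos <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  pos[1:2] <- c(TRUE, FALSE)
  cv <- roc_curve(scores, pos)
  expect_true(all(cv$sensitivity >= 0 & cv$sensitivity <= 1))
  expect_true(all(diff(cv$sensitivity) <= 1e-12))  # sens falls as cutoff rises
  expect_true(all(diff(cv$specificity) >= -1e-12))
})

test_that("Youden cutoff matches exhaustive search with documented ties", {
  set.seed(12)
  for (i in 1:300) {
    n <- sample(5:60, 1)
    pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(rnorm(n), sample(0:1, 1))
    cv <- roc_curve(scores, pos)
    yo <- youden_optimal_cutoff(cv)
    expect_equal(yo$j, bf_youden_j(scores, pos), tolerance = 1e-12)
    # the reported operating point is realized by the "> cutoff" rule
    pred <- scores > yo$cutoff
    expect_equal(sum(pred & pos) / sum(pos), yo$sensitivity)
    expect_equal(sum(!pred & !pos) / sum(!pos), yo$specificity)
  }
})

test_that("Youden behaviour on degenerate and separated data", {
  # perfect separation: any cutoff in [2, 3) under ">" gives J = 1;
  # observed-value convention reports 2, midpoint convention 2.5
  scores <- c(1, 2, 3, 4); pos <- c(FALSE, FALSE, TRUE, TRUE)
  yo <- youden_optimal_cutoff(roc_curve(scores, pos))
  expect_equal(yo$j, 1)
  expect_equal(yo$cutoff, 2)
  expect_true(all((scores > yo$cutoff) == pos))
  yom <- youden_optimal_cutoff(roc_curve(scores, pos), "midpoint")
  expect_equal(yom$cutoff, 2.5)
  expect_true(all((scores > yom$cutoff) == pos))
  # a single shared score value cannot discriminate
  yo0 <- youden_optimal_cutoff(roc_curve(rep(7, 8),
                                         rep(c(TRUE, FALSE), 4)))
  expect_equal(yo0$j, 0)
})

test_that("evaluate_at_cutoff counts the confusion matrix", {
  crit <- criterion("rs_difference", 10, "greater")
  perfect <- evaluate_at_cutoff(c(20, 25, 1, 2),
                                c("LVOT-ASC", "LVOT-ASC", "s-RVOT",
                                  "s-RVOT"), crit)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  all_pos <- evaluate_at_cutoff(c(20, 25, 30, 40),
                                c("LVOT-ASC", "LVOT-ASC", "s-RVOT",
                                  "s-RVOT"), crit)
  expect_equal(all_pos$sensitivity, 100)
  expect_equal(all_pos$specificity, 0)
  # known confusion (tp=3, fp=1, fn=2, tn=4) -> 60% / 80%
  scores <- c(15, 16, 17, 5, 6, 12, 1, 2, 3, 4)
  labels <- rep(c("LVOT-ASC", "s-RVOT"), each = 5)
  ev <- evaluate_at_cutoff(scores, labels, crit)
  expect_equal(unlist(ev[c("tp", "fp", "fn", "tn")]),
               c(tp = 3, fp = 1, fn = 2, tn = 4))
  expect_equal(ev$sensitivity, 60)
  expect_equal(ev$specificity, 80)
})

test_that("diag_criterion fits, predicts and reports consistently", {
  set.seed(6)
  scores <- c(rnorm(60, 2), rnorm(90))
  labels <- rep(c("LVOT-ASC", "s-RVOT"), c(60, 90))
  fit <- diag_criterion(scores, labels, name = "rs_difference")
  expect_s3_class(fit, "diag_criterion")
  expect_equal(fit$youden_j,
               fit$sensitivity / 100 + fit$specificity / 100 - 1)
  expect_equal(unname(coef(fit)["auc"]), fit$auc)
  preds <- predict(fit, c(fit$cutoff, fit$cutoff + 1e-9, NA))
  expect_identical(preds, c("s-RVOT", "LVOT-ASC", "undetermined"))
  expect_output(print(fit), "AUC")
  # NA scores are excluded and counted
  fit2 <- diag_criterion(c(scores, NA, NA), c(labels, "s-RVOT", "LVOT-ASC"))
  expect_equal(fit2$n_excluded, 2)
  expect_equal(fit2$auc, fit$auc)
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("logistic fit matches the 2x2 log-odds closed form", {
  x <- matrix(c(rep(1, 15), rep(0, 15)))
  y <- c(rep("LVOT-ASC", 10), rep("s-RVOT", 5),
         rep("LVOT-ASC", 5), rep("s-RVOT", 10))
  fit <- fit_logistic(x, y)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(log(1 / 2), log(4)), tolerance = 1e-8)
  expect_equal(predict(fit, matrix(c(1, 0)), type = "response"),
               c(10 / 15, 5 / 15), tolerance = 1e-8)
})

test_that("logistic fit flags degeneracies", {
  set.seed(10)
  y <- rep(c(TRUE, FALSE), 25)
  expect_error(fit_logistic(matrix(1, 50, 1), y), "degenerate design")
  x <- matrix(rnorm(50))
  expect_error(fit_logistic(cbind(x, 2 * x), y), "degenerate design")
  # feature balanced within both classes: slope exactly zero at the MLE
  fit0 <- fit_logistic(matrix(rep(c(1, 0, 1, 0), 10)),
                       rep(c(TRUE, TRUE, FALSE, FALSE), 10))
  expect_lt(abs(coef(fit0)[2]), 1e-6)
  # complete separation: monotone likelihood, flagged non-converged
  xs <- matrix(c(1:10))
  ys <- rep(c(FALSE, TRUE), each = 5)
  fits <- suppressWarnings(fit_logistic(xs, ys))
  expect_true(fits$separation)
  expect_false(fits$converged)
})

test_that("fitted logistic score dominates single features in-sample", {
  coh <- small_cohort(40, 30, seed = 3)
  jm <- joint_rs_model(coh)
  labels <- cohort_origins(coh)
  feats <- c(V2R = "r", V3R = "r", V4R = "r", V1S = "s")
  leads <- c(V2R = "V2", V3R = "V3", V4R = "V4", V1S = "V1")
  for (nm in names(feats)) {
    s <- vapply(coh$records,
                function(r) beat_amp(r$pvc, leads[[nm]], feats[[nm]]),
                numeric(1))
    dir <- if (nm == "V1S") "less_equal" else "greater"
    expect_gte(jm$logistic_roc$auc + 1e-9,
               auc_mann_whitney(s, labels, dir))
  }
  expect_true(jm$logistic$converged)
})

test_that("compare_criteria reports oriented AUCs and exclusions", {
  coh <- small_cohort(60, 40, seed = 2)
  cmp <- compare_criteria(coh)
  expect_equal(nrow(cmp), 5)
  expect_setequal(cmp$index, INDEX_NAMES)
  expect_true(all(cmp$auc >= 0.5))  # criteria point the right way
  expect_true(all(cmp$n_used + cmp$n_excluded == 100))
  # reference-cutoff evaluation is reported alongside
  expect_true(all(is.finite(cmp$ref_sensitivity)))
  fits <- attr(cmp, "fits")
  expect_s3_class(fits$rs_difference, "diag_criterion")
})

test_that("compare_criteria on extremes: perfect pair and permuted labels", {
  sinus <- make_beat(V1 = c(0, 1, 6), V2 = c(0, 5, 10), V3 = c(0, 10, 5),
                     beat_type = "sinus")
  two <- new_cohort(list(
    patient_record("a", "s-RVOT", median_beat("s-RVOT"), sinus),
    patient_record("b", "LVOT-ASC", median_beat("LVOT-ASC"), sinus)))
  cmp2 <- compare_criteria(two)
  expect_true(all(cmp2$auc == 1))
  expect_error(compare_criteria(two[1]), "both")

  coh <- small_cohort(100, 100, seed = 13)
  shuffled <- coh
  set.seed(1)
  perm <- sample(cohort_origins(coh))
  for (i in seq_along(shuffled$records))
    shuffled$records[[i]]$origin <- perm[i]
  cmp0 <- compare_criteria(shuffled)
  expect_true(all(abs(cmp0$auc - 0.5) < 0.15))
})

test_that("the R-S difference index has the top AUC across seeds", {
  wins <- 0
  for (seed in 1:5) {
    coh <- small_cohort(90, 40, seed = seed)
    cmp <- compare_criteria(coh)
    if (cmp$auc[cmp$index == "rs_difference"] == max(cmp$auc))
      wins <- wins + 1
  }
  expect_gte(wins, 3)
})
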