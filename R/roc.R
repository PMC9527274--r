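.pos_labels <- function(labels, positive = "LVOT-ASC") {
  pos <- if (is.logical(labels)) labels else as.character(labels) == positive
  if (anyNA(pos)) stop("labels must not contain NA", call. = FALSE)
  if (all(pos) || !any(pos))
    stop("both classes must be present in labels", call. = FALSE)
  pos
}

#' Rank-statistic AUC (Mann-Whitney form)
#'
#' The probability that a random positive-class score exceeds a random
#' negative-class score, ties counted one half, computed from midranks.
#' For `direction = "less_equal"` scores are orientation-flipped first so
#' that the reported AUC always refers to the criterion's own positive
#' direction (and is therefore >= 0.5 whenever the criterion points the
#' right way).
#'
#' @param scores Numeric scores (no NAs).
#' @param labels Class labels; compared against `positive`, or a logical
#'   vector.
#' @param direction `"greater"` if high scores predict the positive class,
#'   `"less_equal"` if low scores do.
#' @param positive Positive class label (default `"LVOT-ASC"`).
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels, direction = c("greater",
                                                           "less_equal"),
                             positive = "LVOT-ASC") {
  direction <- match.arg(direction)
  pos <- .pos_labels(labels, positive)
  if (anyNA(scores)) stop("scores must not contain NA", call. = FALSE)
  s <- if (direction == "less_equal") -scores else scores
  r <- rank(s)  # midranks
  n1 <- sum(pos); n0 <- sum(!pos)
  u <- sum(r[pos]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Operating points are generated by sweeping the cutoff over the observed
#' score values (plus infinite anchors), classifying with the criterion's
#' printed inequality: strictly above the cutoff for
#' `direction = "greater"`, at or below it for `"less_equal"`. The
#' trapezoidal area under the resulting curve equals the rank-statistic
#' AUC exactly.
#'
#' @inheritParams auc_mann_whitney
#' @return An object of class `roc_curve`: a data frame with columns
#'   `threshold`, `sensitivity`, `specificity`, plus attributes `auc`,
#'   `direction`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, direction = c("greater", "less_equal"),
                      positive = "LVOT-ASC") {
  direction <- match.arg(direction)
  pos <- .pos_labels(labels, positive)
  if (anyNA(scores)) stop("scores must not contain NA", call. = FALSE)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  n1 <- sum(pos); n0 <- sum(!pos)
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- if (direction == "greater") scores > thr[i] else scores <= thr[i]
    sens[i] <- sum(pred & pos) / n1
    spec[i] <- sum(!pred & !pos) / n0
  }
  pts <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  # trapezoid over the (fpr, tpr) path, endpoints anchored at (0,0), (1,1)
  ord <- order(1 - pts$specificity, pts$sensitivity)
  fpr <- (1 - pts$specificity)[ord]; tpr <- pts$sensitivity[ord]
  auc_trap <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  structure(pts, class = c("roc_curve", "data.frame"),
            auc = auc_trap, direction = direction, n_pos = n1, n_neg = n0)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f (direction: %s)\n",
              nrow(x), attr(x, "auc"), attr(x, "direction")))
  invisible(x)
}

#' Youden-optimal cutoff of an ROC curve
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the observed
#' (finite) thresholds of the curve. Ties are broken in favour of higher
#' specificity, then the lower cutoff. With `cutoff_mode = "midpoint"`
#' the reported cutoff is shifted to the midpoint between the optimal
#' observed value and the next observed score (the decision rule it
#' induces on the data is unchanged).
#'
#' @param curve A [roc_curve()].
#' @param cutoff_mode `"observed"` (default) or `"midpoint"`.
#' @return List with `cutoff`, `sensitivity`, `specificity`, `j` and
#'   `direction`.
#' @export
youden_optimal_cutoff <- function(curve, cutoff_mode = c("observed",
                                                         "midpoint")) {
  stopifnot(inherits(curve, "roc_curve"))
  cutoff_mode <- match.arg(cutoff_mode)
  fin <- curve[is.finite(curve$threshold), ]
  if (!nrow(fin)) stop("roc curve has no finite thresholds", call. = FALSE)
  j <- fin$sensitivity + fin$specificity - 1
  best <- which(j == max(j))
  best <- best[order(-fin$specificity[best], fin$threshold[best])][1]
  cut <- fin$threshold[best]
  if (cutoff_mode == "midpoint") {
    above <- fin$threshold[fin$threshold > cut]
    if (length(above)) cut <- (cut + min(above)) / 2
  }
  list(cutoff = cut, sensitivity = fin$sensitivity[best],
       specificity = fin$specificity[best], j = max(j),
       direction = attr(curve, "direction"))
}

#' Sensitivity, specificity and confusion counts at a fixed criterion
#'
#' @inheritParams auc_mann_whitney
#' @param crit A [criterion()]; its cutoff and direction define the
#'   decision rule.
#' @return List with `sensitivity` and `specificity` (percent) and the
#'   confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_at_cutoff <- function(scores, labels, crit,
                               positive = "LVOT-ASC") {
  stopifnot(inherits(crit, "criterion"))
  pos <- .pos_labels(labels, positive)
  if (anyNA(scores)) stop("scores must not contain NA", call. = FALSE)
  pred <- if (crit$direction == "greater") scores > crit$cutoff
          else scores <= crit$cutoff
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  list(sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Fit a diagnostic criterion to scored, labeled data
#'
#' The central fitted object of the package: given per-patient index
#' scores and true origin labels, builds the empirical ROC curve, computes
#' the AUC, and (unless a cutoff is supplied) selects the Youden-optimal
#' cutoff, reporting sensitivity and specificity at the operating point.
#' Records with missing (not-computable) scores are excluded and counted.
#'
#' @inheritParams auc_mann_whitney
#' @param name Index name (one of [INDEX_NAMES], or any label for ad-hoc
#'   scores).
#' @param cutoff Optional fixed cutoff; when `NULL` the Youden-optimal
#'   cutoff is fitted.
#' @param cutoff_mode Passed to [youden_optimal_cutoff()].
#' @return An object of class `diag_criterion` with `print`, `summary`,
#'   `coef`, `predict` and `plot` methods.
#' @examples
#' set.seed(1)
#' scores <- c(rnorm(50, 1), rnorm(50))
#' labels <- rep(c("LVOT-ASC", "s-RVOT"), each = 50)
#' fit <- diag_criterion(scores, labels, name = "rs_difference")
#' coef(fit)
#' @export
diag_criterion <- function(scores, labels, name = "score",
                           direction = c("greater", "less_equal"),
                           cutoff = NULL,
                           cutoff_mode = c("observed", "midpoint"),
                           positive = "LVOT-ASC") {
  direction <- match.arg(direction)
  cutoff_mode <- match.arg(cutoff_mode)
  keep <- !is.na(scores)
  n_excluded <- sum(!keep)
  scores <- scores[keep]
  labels <- if (is.logical(labels)) labels[keep] else as.character(labels)[keep]
  pos <- .pos_labels(labels, positive)
  curve <- roc_curve(scores, pos, direction, positive = TRUE)
  auc <- auc_mann_whitney(scores, pos, direction, positive = TRUE)
  fitted_cut <- is.null(cutoff)
  if (fitted_cut) {
    yo <- youden_optimal_cutoff(curve, cutoff_mode)
    cutoff <- yo$cutoff
  }
  ev <- local({
    pred <- if (direction == "greater") scores > cutoff else scores <= cutoff
    tp <- sum(pred & pos); fp <- sum(pred & !pos)
    fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
    list(sensitivity = 100 * tp / (tp + fn),
         specificity = 100 * tn / (tn + fp), tp = tp, fp = fp, fn = fn,
         tn = tn)
  })
  structure(list(
    name = name, direction = direction, positive_class = positive,
    cutoff = cutoff, cutoff_fitted = fitted_cut, cutoff_mode = cutoff_mode,
    auc = auc, roc = curve,
    sensitivity = ev$sensitivity, specificity = ev$specificity,
    youden_j = ev$sensitivity / 100 + ev$specificity / 100 - 1,
    confusion = c(tp = ev$tp, fp = ev$fp, fn = ev$fn, tn = ev$tn),
    n = length(scores), n_excluded = n_excluded,
    scores = scores, positives = pos), class = "diag_criterion")
}

#' @export
print.diag_criterion <- function(x, ...) {
  op <- if (x$direction == "greater") ">" else "<="
  cat(sprintf("Diagnostic criterion: %s %s %.4g predicts %s\n", x$name, op,
              x$cutoff, x$positive_class))
  cat(sprintf("  AUC %.3f | sensitivity %.1f%% | specificity %.1f%% | J %.3f\n",
              x$auc, x$sensitivity, x$specificity, x$youden_j))
  cat(sprintf("  n = %d (excluded: %d); cutoff %s\n", x$n, x$n_excluded,
              if (x$cutoff_fitted) sprintf("Youden-optimal (%s)",
                                           x$cutoff_mode) else "fixed"))
  invisible(x)
}

#' @export
summary.diag_criterion <- function(object, ...) {
  print(object)
  cat("\nConfusion at cutoff:\n")
  print(object$confusion)
  invisible(object)
}

#' @export
coef.diag_criterion <- function(object, ...) {
  c(cutoff = object$cutoff, auc = object$auc,
    sensitivity = object$sensitivity, specificity = object$specificity,
    youden_j = object$youden_j)
}

#' Predict origin class for new index scores
#'
#' @param object A [diag_criterion()] fit.
#' @param newdata Numeric vector of index scores; `NA` scores yield
#'   `"undetermined"`.
#' @param ... Unused.
#' @return Character vector in `{positive class, "s-RVOT", "undetermined"}`.
#' @export
predict.diag_criterion <- function(object, newdata, ...) {
  out <- rep("undetermined", length(newdata))
  known <- !is.na(newdata)
  pred <- if (object$direction == "greater") newdata[known] > object$cutoff
          else newdata[known] <= object$cutoff
  out[known] <- ifelse(pred, object$positive_class, "s-RVOT")
  out
}

#' Plot the ROC curve of a fitted criterion
#'
#' @param x A [diag_criterion()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.diag_criterion <- function(x, ...) {
  fpr <- 1 - x$roc$specificity
  ord <- order(fpr, x$roc$sensitivity)
  graphics::plot(fpr[ord], x$roc$sensitivity[ord], type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("%s (AUC %.3f)", x$name, x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::points(1 - x$specificity / 100, x$sensitivity / 100, pch = 19,
                   col = "red3")
  invisible(x)
}

#' Compare all five origin criteria on a labeled cohort
#'
#' Computes every index for every record, fits a [diag_criterion()] per
#' index (re-optimizing the cutoff by the Youden rule), and also evaluates
#' sensitivity/specificity at the supplied reference cutoffs. Records with
#' a non-computable index are excluded for that index only, with the
#' exclusion count reported.
#'
#' @param cohort A labeled [new_cohort()] with both classes present.
#' @param criteria Named list of reference [criterion()]s (default
#'   [default_criteria()]).
#' @param cutoff_mode Passed to [youden_optimal_cutoff()].
#' @return A `data.frame` of class `criterion_comparison`, one row per
#'   index, with the fitted `diag_criterion` objects in attribute
#'   `"fits"`.
#' @export
compare_criteria <- function(cohort, criteria = default_criteria(),
                             cutoff_mode = c("observed", "midpoint")) {
  cutoff_mode <- match.arg(cutoff_mode)
  stopifnot(inherits(cohort, "pvc_cohort"))
  org <- cohort_origins(cohort)
  keep <- org != "unknown"
  if (!all(c("s-RVOT", "LVOT-ASC") %in% org[keep]))
    stop("compare_criteria: cohort must contain labeled records of both ",
         "classes", call. = FALSE)
  idx <- cohort_indices(cohort[which(keep)], criteria)
  fits <- list(); rows <- list()
  for (nm in names(criteria)) {
    crit <- criteria[[nm]]
    scores <- idx[[nm]]
    labels <- idx$origin
    fit <- diag_criterion(scores, labels, name = nm,
                          direction = crit$direction,
                          cutoff_mode = cutoff_mode)
    ok <- !is.na(scores)
    ref <- evaluate_at_cutoff(scores[ok], labels[ok], crit)
    fits[[nm]] <- fit
    rows[[nm]] <- data.frame(
      index = nm, direction = crit$direction, n_used = fit$n,
      n_excluded = fit$n_excluded, auc = fit$auc, cutoff = fit$cutoff,
      sensitivity = fit$sensitivity, specificity = fit$specificity,
      youden_j = fit$youden_j, ref_cutoff = crit$cutoff,
      ref_sensitivity = ref$sensitivity, ref_specificity = ref$specificity,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("criterion_comparison", "data.frame"),
            fits = fits)
}

#' @export
print.criterion_comparison <- function(x, ...) {
  cat("Comparison of origin-discrimination criteria",
      "(positive class: LVOT-ASC)\n\n")
  show <- x[, c("index", "auc", "cutoff", "sensitivity", "specificity",
                "n_used", "n_excluded")]
  print.data.frame(show, digits = 3, row.names = FALSE)
  invisible(x)
}
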