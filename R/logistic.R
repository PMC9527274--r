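#' Binary logistic regression for origin modelling
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares ([stats::glm.fit()]). Rank-deficient designs (constant or
#' collinear features) are rejected with an error; (quasi-)complete
#' separation is detected via a monotone-likelihood diagnostic (fitted
#' probabilities collapsing to 0/1) and flagged as non-converged.
#'
#' @param features Numeric matrix or data frame of predictors (one row per
#'   observation); an intercept is added internally.
#' @param labels Class labels; `positive` maps to 1. Both classes must be
#'   present.
#' @param positive Positive class label (default `"LVOT-ASC"`).
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the relative deviance change.
#' @return An object of class `origin_logit` with elements
#'   `coefficients`, `converged`, `separation`, `n_iterations`,
#'   `linear_score` (the fitted linear predictor, usable as an ROC input)
#'   and `deviance`.
#' @examples
#' x <- c(rep(1, 15), rep(0, 15))
#' y <- c(rep("LVOT-ASC", 10), rep("s-RVOT", 5),
#'        rep("LVOT-ASC", 5), rep("s-RVOT", 10))
#' fit <- fit_logistic(matrix(x), y)
#' coef(fit)  # slope log(4), intercept -log(2)
#' @export
fit_logistic <- function(features, labels, positive = "LVOT-ASC",
                         max_iter = 100L, tol = 1e-10) {
  x <- as.matrix(features)
  if (!is.numeric(x)) stop("features must be numeric", call. = FALSE)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(.pos_labels(labels, positive))
  if (nrow(x) != length(y))
    stop("features and labels differ in length", call. = FALSE)
  xd <- cbind(`(Intercept)` = 1, x)
  if (qr(xd)$rank < ncol(xd))
    stop("degenerate design: constant or collinear feature column",
         call. = FALSE)
  # muffle glm.fit's boundary warning: separation is detected and flagged
  # explicitly below
  fit <- withCallingHandlers(
    stats::glm.fit(xd, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = tol,
                                                maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  eps <- 1e-8
  separation <- all(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  structure(list(
    coefficients = stats::coef(fit),
    converged = fit$converged && !separation,
    separation = separation,
    n_iterations = fit$iter,
    deviance = fit$deviance,
    linear_score = drop(xd %*% stats::coef(fit)),
    feature_names = colnames(x), positive_class = positive),
    class = "origin_logit")
}

#' @export
print.origin_logit <- function(x, ...) {
  cat(sprintf("Logistic origin model (positive class: %s)\n",
              x$positive_class))
  print(round(x$coefficients, 4))
  cat(sprintf("converged: %s (%d IRLS iterations)%s\n", x$converged,
              x$n_iterations,
              if (x$separation) "; complete separation detected" else ""))
  invisible(x)
}

#' @export
coef.origin_logit <- function(object, ...) object$coefficients

#' Predicted linear score (log-odds) for new feature rows
#'
#' @param object An `origin_logit` fit.
#' @param newdata Numeric matrix with the same columns as the training
#'   features; when omitted the training linear scores are returned.
#' @param type `"link"` for log-odds, `"response"` for probabilities.
#' @param ... Unused.
#' @export
predict.origin_logit <- function(object, newdata = NULL,
                                 type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newdata)) object$linear_score
  else drop(cbind(1, as.matrix(newdata)) %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' Joint models of the four R-S index amplitudes
#'
#' Builds the two readings of a "joint model" over the PVC amplitudes
#' V2R, V3R, V4R and V1S on a labeled cohort, and ROC-evaluates both:
#' \describe{
#'   \item{fixed-weight index}{the R-S difference index, i.e. the linear
#'     combination with weights +1, +1, +1, -1 — no fitting;}
#'   \item{fitted logistic}{a logistic regression of origin on the four
#'     amplitudes, scored by its linear predictor.}
#' }
#' In-sample, the likelihood-fitted score can only improve on any fixed
#' linear combination of the same features in deviance terms, and its AUC
#' is typically at least as large.
#'
#' @param cohort A labeled [new_cohort()] with both classes.
#' @return List of class `joint_rs_model` with elements `fixed`
#'   (a [diag_criterion()] on the R-S difference index), `logistic`
#'   (the `origin_logit` fit) and `logistic_roc` (a [diag_criterion()] on
#'   its linear score).
#' @export
joint_rs_model <- function(cohort) {
  stopifnot(inherits(cohort, "pvc_cohort"))
  keep <- cohort_origins(cohort) != "unknown"
  cohort <- cohort[which(keep)]
  labels <- cohort_origins(cohort)
  feat <- t(vapply(cohort$records, function(rec) c(
    V2R = beat_amp(rec$pvc, "V2", "r"), V3R = beat_amp(rec$pvc, "V3", "r"),
    V4R = beat_amp(rec$pvc, "V4", "r"), V1S = beat_amp(rec$pvc, "V1", "s")),
    numeric(4)))
  fixed_score <- feat[, "V2R"] + feat[, "V3R"] + feat[, "V4R"] -
    feat[, "V1S"]
  fixed <- diag_criterion(fixed_score, labels, name = "rs_difference")
  lg <- fit_logistic(feat, labels)
  lroc <- diag_criterion(lg$linear_score, labels, name = "joint_logistic")
  structure(list(fixed = fixed, logistic = lg, logistic_roc = lroc),
            class = "joint_rs_model")
}

#' @export
print.joint_rs_model <- function(x, ...) {
  cat("Joint model of V2R, V3R, V4R, V1S\n\n")
  cat(sprintf("fixed-weight R-S difference index: AUC %.3f (cutoff %.4g)\n",
              x$fixed$auc, x$fixed$cutoff))
  cat(sprintf("fitted logistic combination:       AUC %.3f\n",
              x$logistic_roc$auc))
  invisible(x)
}
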