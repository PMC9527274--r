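#' Median and quartiles of a numeric vector
#'
#' Empirical quartiles by linear interpolation between order statistics
#' (the type-7 convention of [stats::quantile()]), the common default of
#' statistical packages.
#'
#' @param values Non-empty numeric vector (NAs dropped).
#' @return Named numeric vector `c(q25, q50, q75)`.
#' @examples
#' median_quartiles(1:5)  # 2 3 4
#' @export
median_quartiles <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("median_quartiles: empty input", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q25 = q[1], q50 = q[2], q75 = q[3])
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U test with midrank handling of ties. The exact
#' null distribution is enumerated when the combined sample size is at
#' most 12 and there are no ties; otherwise the normal approximation with
#' tie-corrected variance and continuity correction is used. The returned
#' U statistic counts pairs in which `a` exceeds `b` (ties count one
#' half), so `U / (length(a) * length(b))` is the AUC of `a` against `b`.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with `U` and two-sided `p_value`.
#' @export
rank_sum_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop("rank_sum_test: both groups must be non-empty", call. = FALSE)
  if (length(unique(c(a, b))) == 1L)  # all tied: no evidence either way
    return(list(U = length(a) * length(b) / 2, p_value = 1))
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Independent two-sample t-test
#'
#' Student's pooled-variance test by default, Welch's unequal-variance
#' variant with `welch = TRUE`. Degenerate inputs are handled explicitly:
#' when both groups are constant, equal means give t = 0, p = 1 and
#' unequal means give an infinite statistic with p = 0.
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @param welch Use the Welch variant?
#' @return List with `t` and two-sided `p_value`.
#' @export
t_test <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("t_test: each group needs at least 2 values", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    d <- mean(a) - mean(b)
    if (d == 0) return(list(t = 0, p_value = 1))
    return(list(t = sign(d) * Inf, p_value = 0))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), p_value = tt$p.value)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square without continuity correction, df = 1. Equivalent
#' to the closed form n(ad - bc)^2 / (r1 r2 c1 c2).
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   marginals.
#' @return List with `chi_square`, `df` and `p_value`.
#' @examples
#' # gender split by origin group: 54/129 males/females vs 41/35
#' chi_square_test(matrix(c(54, 41, 129, 35), nrow = 2))  # X2 = 13.81
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("chi_square_test: need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("chi_square_test: counts must be non-negative integers",
         call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi_square_test: zero marginal", call. = FALSE)
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chi_square = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Group-comparison summary table of a labeled cohort
#'
#' Reproduces the shape of a per-lead ECG measurement comparison: for each
#' lead and each of Q/R/S amplitude and QRS duration of the PVC beat, the
#' median (q25, q75) in each origin group and the two-sided rank-sum p
#' value. Records with origin `"unknown"` are excluded. If a `gender`
#' covariate is present a chi-square row is appended.
#'
#' @param cohort A [new_cohort()] object with both origin groups present.
#' @return A `data.frame` with one row per (lead, measure) plus an
#'   optional gender row; class `cohort_summary`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "pvc_cohort"))
  df <- cohort_to_df(cohort)
  df <- df[df$origin != "unknown", ]
  groups <- c("s-RVOT", "LVOT-ASC")
  if (!all(groups %in% df$origin))
    stop("summarize_cohort: need records from both origin groups",
         call. = FALSE)
  measures <- c(q = "Q amplitude", r = "R amplitude", s = "S amplitude",
                qrsd = "QRS duration")
  rows <- list()
  fmt <- function(q) sprintf("%.4g (%.4g,%.4g)", q[2], q[1], q[3])
  for (ld in ECG_LEADS) {
    for (w in names(measures)) {
      col <- paste(ld, "pvc", .wave_suffixes[[w]], sep = "_")
      va <- df[[col]][df$origin == "s-RVOT"]
      vb <- df[[col]][df$origin == "LVOT-ASC"]
      qa <- median_quartiles(va); qb <- median_quartiles(vb)
      p <- rank_sum_test(va, vb)$p_value
      rows[[length(rows) + 1L]] <- data.frame(
        lead = ld, measure = measures[[w]], test = "rank_sum",
        srvot = fmt(qa), lvot_asc = fmt(qb),
        srvot_q50 = unname(qa["q50"]), lvot_asc_q50 = unname(qb["q50"]),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if ("gender" %in% names(df)) {
    tab <- table(factor(df$origin, groups), df$gender)
    if (all(dim(tab) == c(2L, 2L)) && all(rowSums(tab) > 0) &&
        all(colSums(tab) > 0)) {
      cs <- suppressWarnings(chi_square_test(unclass(tab)[, , drop = FALSE]))
      out <- rbind(out, data.frame(
        lead = "-", measure = "gender", test = "chi_square",
        srvot = paste(tab["s-RVOT", ], collapse = "/"),
        lvot_asc = paste(tab["LVOT-ASC", ], collapse = "/"),
        srvot_q50 = NA_real_, lvot_asc_q50 = NA_real_,
        p_value = cs$p_value, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Group comparison of ECG measurements (PVC beat)\n")
  cat("values: median (q25,q75); p: two-sided rank-sum",
      "(chi-square for counts)\n\n")
  print.data.frame(x[, c("lead", "measure", "srvot", "lvot_asc", "p_value")],
                   digits = 3, row.names = FALSE)
  invisible(x)
}
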