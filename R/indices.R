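#' Names of the implemented origin-discrimination indices
#' @format Character vector of length 5.
#' @export
INDEX_NAMES <- c("rs_difference", "v2s_v3r", "rv1v3_transition_ratio",
                 "v2_transition_ratio", "s_minus_r_v1v2")

index_value <- function(name, value = NA_real_, computable = TRUE,
                        note = "") {
  if (!computable) value <- NA_real_
  structure(list(name = name, value = value,
                 computable = computable && !is.na(value), note = note),
            class = "index_value")
}

#' @export
print.index_value <- function(x, ...) {
  if (x$computable)
    cat(sprintf("<index_value> %s = %g\n", x$name, x$value))
  else
    cat(sprintf("<index_value> %s: not computable (%s)\n", x$name, x$note))
  invisible(x)
}

#' Precordial R-S difference index (V2R + V3R + V4R - V1S)
#'
#' The sum of the PVC R-wave amplitudes in leads V2-V4 minus the PVC S-wave
#' amplitude in lead V1. LVOT-ASC PVCs, arising leftward and posterior of
#' the septal RVOT, project larger precordial R waves and a smaller V1 S
#' wave, so large values point to an aortic-sinus-cusp origin. Values above
#' 20.9 au predict LVOT-ASC; values at or below predict s-RVOT.
#'
#' @param pvc A [beat_measurement()] of the PVC beat.
#' @return An `index_value` (always computable).
#' @examples
#' # group-median LVOT-ASC beat: 6.95 + 12.55 + 18.5 - 8.1 = 29.9
#' @export
rs_difference_index <- function(pvc) {
  stopifnot(inherits(pvc, "beat_measurement"))
  v <- beat_amp(pvc, "V2", "r") + beat_amp(pvc, "V3", "r") +
    beat_amp(pvc, "V4", "r") - beat_amp(pvc, "V1", "s")
  index_value("rs_difference", v)
}

#' V2S/V3R index
#'
#' Ratio of the PVC S-wave amplitude in V2 to the PVC R-wave amplitude in
#' V3. Small values (<= 1.44) predict LVOT-ASC. When V3R = 0 but V2S > 0
#' the ratio is `+Inf` (decisively on the s-RVOT side); when both are 0 the
#' index is not computable.
#'
#' @inheritParams rs_difference_index
#' @return An `index_value`.
#' @export
v2s_v3r_index <- function(pvc) {
  stopifnot(inherits(pvc, "beat_measurement"))
  num <- beat_amp(pvc, "V2", "s")
  den <- beat_amp(pvc, "V3", "r")
  if (den == 0 && num == 0)
    return(index_value("v2s_v3r", computable = FALSE,
                       note = "V2S and V3R both zero"))
  index_value("v2s_v3r", if (den == 0) Inf else num / den)
}

#' RV1-V3 transition ratio
#'
#' Ratio of the summed PVC R-wave amplitudes in V1-V3 to the summed sinus
#' R-wave amplitudes in the same leads. Values above 0.65 predict
#' LVOT-ASC. Requires a paired sinus beat; a zero sinus R-wave sum makes
#' the index not computable.
#'
#' @inheritParams rs_difference_index
#' @param sinus A [beat_measurement()] of the paired sinus beat, or `NULL`.
#' @return An `index_value`.
#' @export
rv1v3_transition_ratio <- function(pvc, sinus) {
  stopifnot(inherits(pvc, "beat_measurement"))
  if (is.null(sinus))
    return(index_value("rv1v3_transition_ratio", computable = FALSE,
                       note = "sinus beat absent"))
  stopifnot(inherits(sinus, "beat_measurement"))
  rsum <- function(b) beat_amp(b, "V1", "r") + beat_amp(b, "V2", "r") +
    beat_amp(b, "V3", "r")
  den <- rsum(sinus)
  if (den == 0)
    return(index_value("rv1v3_transition_ratio", computable = FALSE,
                       note = "sinus V1-V3 R-wave sum is zero"))
  index_value("rv1v3_transition_ratio", rsum(pvc) / den)
}

#' V2 transition ratio
#'
#' The PVC R-wave fraction R/(R+S) in lead V2 divided by the same fraction
#' on the paired sinus beat, amplitudes taken as magnitudes. Values above
#' 0.94 predict LVOT-ASC. Any zero denominator (a flat V2 on either beat,
#' or a sinus V2 with no R wave) makes the index not computable.
#'
#' @inheritParams rv1v3_transition_ratio
#' @return An `index_value`.
#' @export
v2_transition_ratio <- function(pvc, sinus) {
  stopifnot(inherits(pvc, "beat_measurement"))
  if (is.null(sinus))
    return(index_value("v2_transition_ratio", computable = FALSE,
                       note = "sinus beat absent"))
  stopifnot(inherits(sinus, "beat_measurement"))
  frac <- function(b) {
    r <- beat_amp(b, "V2", "r"); s <- beat_amp(b, "V2", "s")
    if (r + s == 0) NA_real_ else r / (r + s)
  }
  fp <- frac(pvc); fs <- frac(sinus)
  if (is.na(fp) || is.na(fs) || fs == 0)
    return(index_value("v2_transition_ratio", computable = FALSE,
                       note = "zero denominator in V2 R/(R+S) ratio"))
  index_value("v2_transition_ratio", fp / fs)
}

#' S-R amplitude difference in V1 and V2: (V1S + V2S) - (V1R + V2R)
#'
#' Summed PVC S-wave minus summed R-wave amplitudes over V1-V2. s-RVOT
#' PVCs carry deeper right-precordial S waves, so large values point to
#' s-RVOT; values at or below 15.7 predict LVOT-ASC.
#'
#' @inheritParams rs_difference_index
#' @return An `index_value` (always computable).
#' @export
s_minus_r_v1v2 <- function(pvc) {
  stopifnot(inherits(pvc, "beat_measurement"))
  v <- beat_amp(pvc, "V1", "s") + beat_amp(pvc, "V2", "s") -
    beat_amp(pvc, "V1", "r") - beat_amp(pvc, "V2", "r")
  index_value("s_minus_r_v1v2", v)
}

#' Precordial transition lead
#'
#' First precordial lead (V1 through V6) where the R/S amplitude ratio
#' exceeds 1. A lead with R > 0 and S = 0 (monophasic R) counts as past
#' transition; an exact R/S = 1 tie does not; leads with R = S = 0 are
#' skipped. Returns `"none"` if no lead qualifies.
#'
#' @inheritParams rs_difference_index
#' @return One of `"V1"` .. `"V6"` or `"none"`.
#' @export
transition_lead <- function(pvc) {
  stopifnot(inherits(pvc, "beat_measurement"))
  for (ld in PRECORDIAL_LEADS) {
    r <- beat_amp(pvc, ld, "r"); s <- beat_amp(pvc, ld, "s")
    if (r == 0 && s == 0) next
    if ((s == 0 && r > 0) || (s > 0 && r / s > 1)) return(ld)
  }
  "none"
}

#' Diagnostic criterion: an index with a cutoff and direction
#'
#' The positive class is always LVOT-ASC. `direction = "greater"` means
#' values strictly above the cutoff predict LVOT-ASC (e.g. R-S difference
#' index > 20.9); `direction = "less_equal"` means values at or below the
#' cutoff do (e.g. V2S/V3R <= 1.44). Boundaries follow the printed
#' inequality exactly: ">" is strict, "<=" inclusive.
#'
#' @param name One of [INDEX_NAMES].
#' @param cutoff Numeric cutoff in the index's own unit.
#' @param direction `"greater"` or `"less_equal"`.
#' @return An object of class `criterion`.
#' @export
criterion <- function(name, cutoff, direction = c("greater", "less_equal")) {
  direction <- match.arg(direction)
  if (!name %in% INDEX_NAMES)
    stop("unknown index name: ", name, call. = FALSE)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, !is.na(cutoff))
  structure(list(name = name, cutoff = cutoff, direction = direction,
                 positive_class = "LVOT-ASC"), class = "criterion")
}

#' @export
print.criterion <- function(x, ...) {
  op <- if (x$direction == "greater") ">" else "<="
  cat(sprintf("<criterion> %s %s %g predicts %s\n", x$name, op, x$cutoff,
              x$positive_class))
  invisible(x)
}

#' Reference criteria with their published cutoff values
#'
#' The five criteria at the cutoff values reported for the s-RVOT vs
#' LVOT-ASC discrimination problem: R-S difference index > 20.9, V2S/V3R
#' <= 1.44, RV1-V3 transition ratio > 0.65, V2 transition ratio > 0.94,
#' (V1S+V2S)-(V1R+V2R) <= 15.7, each predicting an LVOT-ASC origin.
#'
#' @return Named list of [criterion()] objects, one per index.
#' @export
default_criteria <- function() {
  list(
    rs_difference = criterion("rs_difference", 20.9, "greater"),
    v2s_v3r = criterion("v2s_v3r", 1.44, "less_equal"),
    rv1v3_transition_ratio = criterion("rv1v3_transition_ratio", 0.65,
                                       "greater"),
    v2_transition_ratio = criterion("v2_transition_ratio", 0.94, "greater"),
    s_minus_r_v1v2 = criterion("s_minus_r_v1v2", 15.7, "less_equal"))
}

#' Apply a criterion to an index value
#'
#' @param value An `index_value` as returned by the index functions.
#' @param crit A [criterion()] for the same index.
#' @return `"LVOT-ASC"`, `"s-RVOT"`, or `"undetermined"` when the value is
#'   not computable.
#' @export
apply_criterion <- function(value, crit) {
  stopifnot(inherits(value, "index_value"), inherits(crit, "criterion"))
  if (value$name != crit$name)
    stop(sprintf("criterion/value mismatch: %s vs %s", crit$name,
                 value$name), call. = FALSE)
  if (!value$computable) return("undetermined")
  positive <- if (crit$direction == "greater") value$value > crit$cutoff
              else value$value <= crit$cutoff
  if (positive) crit$positive_class else "s-RVOT"
}

#' Compute all five indices for one patient record
#'
#' Sinus-dependent indices (both transition ratios) are marked not
#' computable when the record has no sinus beat.
#'
#' @param record A [patient_record()].
#' @return Named list of `index_value` objects, one per [INDEX_NAMES].
#' @export
compute_all_indices <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  list(
    rs_difference = rs_difference_index(record$pvc),
    v2s_v3r = v2s_v3r_index(record$pvc),
    rv1v3_transition_ratio = rv1v3_transition_ratio(record$pvc, record$sinus),
    v2_transition_ratio = v2_transition_ratio(record$pvc, record$sinus),
    s_minus_r_v1v2 = s_minus_r_v1v2(record$pvc))
}

#' Per-patient index table for a cohort
#'
#' One row per record, in cohort order: the five index values (`NA` when
#' not computable), the precordial transition lead, the V1 morphology
#' label, and the predicted origin under each supplied criterion
#' (columns `pred_<index>`).
#'
#' @param cohort A [new_cohort()] object.
#' @param criteria Named list of [criterion()] objects (default:
#'   [default_criteria()]).
#' @return A `data.frame`.
#' @export
cohort_indices <- function(cohort, criteria = default_criteria()) {
  stopifnot(inherits(cohort, "pvc_cohort"))
  rows <- lapply(cohort$records, function(rec) {
    iv <- compute_all_indices(rec)
    vals <- vapply(iv, function(v) if (v$computable) v$value else NA_real_,
                   numeric(1))
    preds <- vapply(names(criteria), function(nm)
      apply_criterion(iv[[nm]], criteria[[nm]]), character(1))
    names(preds) <- paste0("pred_", names(criteria))
    c(list(patient_id = rec$patient_id, origin = rec$origin),
      as.list(vals),
      list(transition_lead = transition_lead(rec$pvc),
           v1_morphology = classify_v1_morphology(rec$pvc$leads$V1)),
      as.list(preds))
  })
  do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE,
                              make.row.names = FALSE))
}
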