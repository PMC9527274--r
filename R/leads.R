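#' Standard 12-lead ECG lead names, in conventional order
#'
#' Limb leads first, then the precordial leads V1 through V6. The precordial
#' order matters: the transition lead is defined as the first of V1..V6 whose
#' R/S amplitude ratio exceeds 1.
#'
#' @format Character vector of length 12.
#' @export
ECG_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
               "V1", "V2", "V3", "V4", "V5", "V6")

#' Precordial leads V1..V6
#' @format Character vector of length 6.
#' @export
PRECORDIAL_LEADS <- c("V1", "V2", "V3", "V4", "V5", "V6")

#' Recognised PVC origin labels
#' @format Character vector: septal RVOT, aortic sinus cusp, unknown.
#' @export
ORIGIN_LEVELS <- c("s-RVOT", "LVOT-ASC", "unknown")

#' Single-lead wave measurement
#'
#' Holds the Q-, R- and S-wave amplitudes and the QRS duration measured in
#' one ECG lead for one beat. Amplitudes are stored as non-negative
#' magnitudes in "au", the amplitude unit of the calibration tables shipped
#' with the package (most plausibly 0.1 mV, i.e. millimetres of deflection
#' at the standard 10 mm/mV gain); polarity is carried by which field holds
#' the value (Q/S are negative deflections, R positive). A monophasic
#' negative (QS) complex is recorded entirely under `s_amp` with
#' `q_amp = r_amp = 0`. A missing QRS duration is allowed and stored as
#' `NA`.
#'
#' @param q_amp,r_amp,s_amp Non-negative wave amplitude magnitudes (au).
#' @param qrs_duration QRS duration in milliseconds (>= 0), or `NA`.
#' @return An object of class `lead_wave`.
#' @examples
#' lead_wave(q_amp = 0, r_amp = 1.2, s_amp = 11.8, qrs_duration = 120)
#' @export
lead_wave <- function(q_amp = 0, r_amp = 0, s_amp = 0, qrs_duration = NA_real_) {
  amps <- c(q_amp = q_amp, r_amp = r_amp, s_amp = s_amp)
  if (anyNA(amps))
    stop("lead_wave amplitudes must not be NA", call. = FALSE)
  if (any(amps < 0))
    stop("lead_wave amplitudes must be non-negative magnitudes; got ",
         paste(sprintf("%s=%g", names(amps)[amps < 0], amps[amps < 0]),
               collapse = ", "), call. = FALSE)
  if (!is.na(qrs_duration) && qrs_duration < 0)
    stop("qrs_duration must be >= 0 or NA", call. = FALSE)
  structure(list(q_amp = as.numeric(q_amp), r_amp = as.numeric(r_amp),
                 s_amp = as.numeric(s_amp),
                 qrs_duration = as.numeric(qrs_duration)),
            class = "lead_wave")
}

#' @export
print.lead_wave <- function(x, ...) {
  cat(sprintf("<lead_wave> Q=%g R=%g S=%g au, QRSd=%s ms\n",
              x$q_amp, x$r_amp, x$s_amp,
              ifelse(is.na(x$qrs_duration), "NA", format(x$qrs_duration))))
  invisible(x)
}

#' 12-lead beat measurement
#'
#' Bundles one [lead_wave()] per standard lead for a single beat, either a
#' premature ventricular contraction (`"pvc"`) or a conducted sinus beat
#' (`"sinus"`). All 12 standard leads must be present; unknown lead names
#' are rejected.
#'
#' @param beat_type `"pvc"` or `"sinus"`.
#' @param leads Named list mapping every name in [ECG_LEADS] to a
#'   [lead_wave()].
#' @return An object of class `beat_measurement`.
#' @export
beat_measurement <- function(beat_type = c("pvc", "sinus"), leads) {
  beat_type <- match.arg(beat_type)
  if (!is.list(leads) || is.null(names(leads)))
    stop("leads must be a named list of lead_wave objects", call. = FALSE)
  unknown <- setdiff(names(leads), ECG_LEADS)
  if (length(unknown))
    stop("unknown lead name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(ECG_LEADS, names(leads))
  if (length(missing))
    stop("missing lead(s): ", paste(missing, collapse = ", "), call. = FALSE)
  ok <- vapply(leads, inherits, logical(1), what = "lead_wave")
  if (!all(ok))
    stop("all leads must be lead_wave objects; offending: ",
         paste(names(leads)[!ok], collapse = ", "), call. = FALSE)
  structure(list(beat_type = beat_type, leads = leads[ECG_LEADS]),
            class = "beat_measurement")
}

#' @export
print.beat_measurement <- function(x, ...) {
  cat(sprintf("<beat_measurement: %s>\n", x$beat_type))
  m <- t(vapply(x$leads, function(lw)
    c(Q = lw$q_amp, R = lw$r_amp, S = lw$s_amp, QRSd = lw$qrs_duration),
    numeric(4)))
  print(m)
  invisible(x)
}

#' Extract an amplitude from a beat
#'
#' Convenience accessor used throughout the index calculations.
#'
#' @param beat A [beat_measurement()].
#' @param lead One of [ECG_LEADS].
#' @param wave `"q"`, `"r"` or `"s"` for an amplitude, `"qrsd"` for the
#'   duration.
#' @return Numeric scalar.
#' @export
beat_amp <- function(beat, lead, wave = c("r", "s", "q", "qrsd")) {
  wave <- match.arg(wave)
  stopifnot(inherits(beat, "beat_measurement"), lead %in% ECG_LEADS)
  lw <- beat$leads[[lead]]
  switch(wave, q = lw$q_amp, r = lw$r_amp, s = lw$s_amp,
         qrsd = lw$qrs_duration)
}

#' Per-patient record: paired PVC and sinus beats with origin label
#'
#' @param patient_id Unique identifier string.
#' @param origin One of `"s-RVOT"`, `"LVOT-ASC"`, `"unknown"`.
#' @param pvc A [beat_measurement()] with `beat_type = "pvc"`.
#' @param sinus Optional [beat_measurement()] with `beat_type = "sinus"`;
#'   sinus-dependent indices are reported as not computable when absent.
#' @param covariates Named list of clinical covariates (e.g. `age`,
#'   `gender`).
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, origin = "unknown", pvc, sinus = NULL,
                           covariates = list()) {
  if (!is.character(patient_id) || length(patient_id) != 1L ||
      is.na(patient_id) || !nzchar(patient_id))
    stop("patient_id must be a non-empty string", call. = FALSE)
  if (!origin %in% ORIGIN_LEVELS)
    stop("origin must be one of ", paste(ORIGIN_LEVELS, collapse = ", "),
         call. = FALSE)
  if (!inherits(pvc, "beat_measurement") || pvc$beat_type != "pvc")
    stop("pvc must be a beat_measurement with beat_type 'pvc'", call. = FALSE)
  if (!is.null(sinus) &&
      (!inherits(sinus, "beat_measurement") || sinus$beat_type != "sinus"))
    stop("sinus must be NULL or a beat_measurement with beat_type 'sinus'",
         call. = FALSE)
  structure(list(patient_id = patient_id, origin = origin, pvc = pvc,
                 sinus = sinus, covariates = covariates),
            class = "patient_record")
}

#' Cohort of patient records
#'
#' An ordered collection of [patient_record()]s with unique patient ids.
#'
#' @param records List of [patient_record()] objects.
#' @return An object of class `pvc_cohort`.
#' @seealso [read_cohort()], [write_cohort()], [generate_cohort()]
#' @export
new_cohort <- function(records = list()) {
  ok <- vapply(records, inherits, logical(1), what = "patient_record")
  if (length(records) && !all(ok))
    stop("all elements must be patient_record objects", call. = FALSE)
  ids <- vapply(records, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids))
    stop("duplicate patient_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(list(records = records), class = "pvc_cohort")
}

#' @export
length.pvc_cohort <- function(x) length(x$records)

#' @export
`[[.pvc_cohort` <- function(x, i) x$records[[i]]

#' @export
`[.pvc_cohort` <- function(x, i) new_cohort(x$records[i])

#' @export
print.pvc_cohort <- function(x, ...) {
  org <- cohort_origins(x)
  cat(sprintf("<pvc_cohort> %d patients (%s)\n", length(x),
              paste(sprintf("%s: %d", names(table(org)), table(org)),
                    collapse = ", ")))
  has_sinus <- sum(vapply(x$records, function(r) !is.null(r$sinus), logical(1)))
  cat(sprintf("  paired sinus beats: %d/%d\n", has_sinus, length(x)))
  invisible(x)
}

#' Origin labels of a cohort
#' @param cohort A `pvc_cohort`.
#' @return Character vector of origin labels, one per record.
#' @export
cohort_origins <- function(cohort) {
  stopifnot(inherits(cohort, "pvc_cohort"))
  vapply(cohort$records, `[[`, character(1), "origin")
}

#' Classify the QRS morphology of lead V1
#'
#' Assigns the conventional shorthand pattern for the V1 complex from the
#' measured wave magnitudes. Lower-case letters denote small deflections
#' relative to the dominant one; here the labels are defined purely by which
#' waves are present and the R-vs-S dominance:
#' \describe{
#'   \item{qrS}{all three waves present (q > 0, r > 0, s > 0)}
#'   \item{rS}{no q wave, r and s present, r < s (S-dominant)}
#'   \item{QS}{monophasic negative: r = 0, s > 0 (recorded under S), q = 0}
#'   \item{Rs}{no q wave, r >= s > 0 (R-dominant biphasic)}
#'   \item{R}{monophasic positive: r > 0, q = s = 0}
#'   \item{other}{anything else (e.g. isolated Q, flat line, qR patterns)}
#' }
#' In outflow-tract PVCs with a left-bundle-branch-block pattern, V1 is
#' S-dominant, so rS and QS dominate.
#'
#' @param v1 A [lead_wave()] for lead V1.
#' @return One of `"rS"`, `"QS"`, `"qrS"`, `"Rs"`, `"R"`, `"other"`.
#' @examples
#' classify_v1_morphology(lead_wave(q_amp = 0, r_amp = 1.2, s_amp = 11.8))  # rS
#' @export
classify_v1_morphology <- function(v1) {
  stopifnot(inherits(v1, "lead_wave"))
  q <- v1$q_amp; r <- v1$r_amp; s <- v1$s_amp
  if (q > 0 && r > 0 && s > 0) return("qrS")
  if (q == 0 && r > 0 && s > 0 && r < s) return("rS")
  if (q == 0 && r == 0 && s > 0) return("QS")
  if (q == 0 && r >= s && s > 0) return("Rs")
  if (q == 0 && r > 0 && s == 0) return("R")
  "other"
}
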