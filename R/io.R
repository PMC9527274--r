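.wave_suffixes <- c(q = "q_amp", r = "r_amp", s = "s_amp", qrsd = "qrsd_ms")

.beat_columns <- function(beat) {
  unlist(lapply(ECG_LEADS, function(ld)
    paste(ld, beat, .wave_suffixes, sep = "_")), use.names = FALSE)
}

#' Convert a cohort to a wide data frame
#'
#' One row per patient. Measurement columns are named
#' `{lead}_{beat}_{q|r|s}_amp` and `{lead}_{beat}_qrsd_ms` for
#' `beat` in `pvc`, `sinus`; covariates keep their own names. Records
#' without a sinus beat get `NA` in all sinus columns.
#'
#' @param cohort A [new_cohort()] object.
#' @return A `data.frame` with `patient_id`, `origin`, 96 measurement
#'   columns and any covariate columns.
#' @export
cohort_to_df <- function(cohort) {
  stopifnot(inherits(cohort, "pvc_cohort"))
  n <- length(cohort)
  beat_cols <- c(.beat_columns("pvc"), .beat_columns("sinus"))
  m <- matrix(NA_real_, nrow = n, ncol = length(beat_cols),
              dimnames = list(NULL, beat_cols))
  cov_names <- unique(unlist(lapply(cohort$records,
                                    function(r) names(r$covariates))))
  covs <- lapply(cov_names, function(nm) rep(NA, n))
  names(covs) <- cov_names
  for (i in seq_len(n)) {
    rec <- cohort[[i]]
    for (beat in c("pvc", "sinus")) {
      bm <- rec[[beat]]
      if (is.null(bm)) next
      for (ld in ECG_LEADS) {
        lw <- bm$leads[[ld]]
        m[i, paste(ld, beat, .wave_suffixes, sep = "_")] <-
          c(lw$q_amp, lw$r_amp, lw$s_amp, lw$qrs_duration)
      }
    }
    for (nm in names(rec$covariates))
      covs[[nm]][i] <- rec$covariates[[nm]]
  }
  out <- data.frame(
    patient_id = vapply(cohort$records, `[[`, character(1), "patient_id"),
    origin = cohort_origins(cohort),
    m, check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in cov_names) out[[nm]] <- unlist(covs[[nm]])
  out
}

.row_to_beat <- function(row, beat, rowid) {
  cols <- .beat_columns(beat)
  vals <- as.numeric(row[cols])
  if (beat == "sinus" && all(is.na(vals))) return(NULL)
  leads <- list()
  for (ld in ECG_LEADS) {
    v <- as.numeric(row[paste(ld, beat, .wave_suffixes, sep = "_")])
    if (anyNA(v[1:3]))
      stop(sprintf("row '%s': missing %s amplitude in lead %s", rowid, beat,
                   ld), call. = FALSE)
    if (any(v[1:3] < 0))
      stop(sprintf("row '%s': negative %s amplitude in lead %s", rowid, beat,
                   ld), call. = FALSE)
    leads[[ld]] <- lead_wave(v[1], v[2], v[3], v[4])
  }
  beat_measurement(beat, leads)
}

#' Read a cohort from a wide CSV file
#'
#' The expected table is comma-separated, UTF-8, with a mandatory header
#' row; empty cells are missing values. Mandatory columns: `patient_id`,
#' `origin` and the 48 PVC measurement columns (see [cohort_to_df()] for
#' the naming scheme). Sinus columns are optional as a block: if any is
#' present all 48 must be; a record whose sinus cells are all empty has no
#' sinus beat. Any other column that does not look like a measurement
#' column is kept as a covariate.
#'
#' @param path Path to the CSV file.
#' @return A [new_cohort()] object.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("patient_id", "origin", .beat_columns("pvc"))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort table schema error; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sinus_cols <- .beat_columns("sinus")
  has_sinus <- any(sinus_cols %in% names(df))
  if (has_sinus) {
    ms <- setdiff(sinus_cols, names(df))
    if (length(ms))
      stop("cohort table schema error; incomplete sinus block, missing: ",
           paste(ms, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), c(required, sinus_cols))
  bad <- grep(sprintf("_(pvc|sinus)_(%s)$",
                      paste(.wave_suffixes, collapse = "|")), extra,
              value = TRUE)
  if (length(bad))
    stop("cohort table schema error; unknown measurement column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    id <- as.character(row[["patient_id"]])
    origin <- as.character(row[["origin"]])
    if (!origin %in% ORIGIN_LEVELS)
      stop(sprintf("row '%s': unknown origin label '%s'", id, origin),
           call. = FALSE)
    pvc <- .row_to_beat(row, "pvc", id)
    sinus <- if (has_sinus) .row_to_beat(row, "sinus", id) else NULL
    covs <- lapply(extra, function(nm) row[[nm]])
    names(covs) <- extra
    covs <- covs[!vapply(covs, function(v) is.na(v) || identical(v, ""),
                         logical(1))]
    records[[i]] <- patient_record(id, origin, pvc, sinus, covs)
  }
  new_cohort(records)
}

#' Write a cohort to a wide CSV file
#'
#' Inverse of [read_cohort()]: the written file reads back into an
#' identical cohort, and re-writing a just-read file reproduces it
#' byte-for-byte.
#'
#' @param cohort A [new_cohort()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort_to_df(cohort)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
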