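# Domain model: cohorts of patients with dated physician claims, hospital/ER
# records, drug claims, and chart-review reference labels, plus the CSV
# readers/writers for the five-file on-disk layout.

SETTINGS <- c("INPATIENT", "ER")
LABEL_STATUSES <- c("DEFINITE_RA", "POSSIBLE_RA", "NON_RA")
SEXES <- c("F", "M")

#' Default observation window and index date
#'
#' Administrative data are observed from 1991-04-01 through 2011-03-31; ages
#' (for the adult/senior analysis subsets and the drug-claim age restriction)
#' are computed at the index date 2010-12-31.
#' @keywords internal
#' @name cohort_defaults
DEFAULT_OBS_START <- as.Date("1991-04-01")
DEFAULT_OBS_END <- as.Date("2011-03-31")
DEFAULT_INDEX_DATE <- as.Date("2010-12-31")

parse_iso_date <- function(x, what, allow_na = FALSE) {
  x <- as.character(x)
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !(allow_na & (is.na(x) | !nzchar(x))))
  if (length(bad)) {
    stop(
      "unparseable ISO 8601 date(s) in ", what, " at row(s) ",
      paste(utils::head(bad, 5L), collapse = ", "),
      if (length(bad) > 5L) " ..." else "",
      ": ", paste(utils::head(x[bad], 5L), collapse = ", ")
    )
  }
  d
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", what, ": ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

check_window <- function(dates, obs_start, obs_end, what) {
  bad <- which(dates < obs_start | dates > obs_end)
  if (length(bad)) {
    stop(
      "event date(s) outside observation window [", obs_start, ", ", obs_end,
      "] in ", what, " at row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
      if (length(bad) > 5L) " ..." else ""
    )
  }
  invisible(dates)
}

check_enum <- function(x, allowed, what) {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad)) {
    stop("invalid ", what, ": ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  invisible(x)
}

check_known_patients <- function(ids, known, what) {
  bad <- setdiff(unique(ids), known)
  if (length(bad)) {
    stop(
      "row(s) in ", what, " reference unknown patient_id(s): ",
      paste(utils::head(bad, 5L), collapse = ", "),
      if (length(bad) > 5L) " ..." else ""
    )
  }
  invisible(ids)
}

empty_claims <- function() {
  data.frame(
    patient_id = character(), service_date = as.Date(character()),
    dx_code = character(), dx_system = character(), specialty = character(),
    stringsAsFactors = FALSE
  )
}

empty_hospital <- function() {
  data.frame(
    patient_id = character(), event_date = as.Date(character()),
    setting = character(), dx_codes = character(), dx_system = character(),
    stringsAsFactors = FALSE
  )
}

empty_drugs <- function() {
  data.frame(
    patient_id = character(), dispense_date = as.Date(character()),
    drug_class = character(), stringsAsFactors = FALSE
  )
}

#' Assemble and validate a claims cohort
#'
#' A cohort bundles the five tables of the on-disk layout: `patients`
#' (patient_id, birth_date, sex), `claims` (physician billing: patient_id,
#' service_date, dx_code, dx_system, specialty — exactly one diagnosis per
#' claim), `hospital` (patient_id, event_date, setting INPATIENT/ER,
#' dx_codes as a semicolon-joined list, dx_system), `drugs` (patient_id,
#' dispense_date, drug_class), and `labels` (patient_id, status
#' DEFINITE_RA/POSSIBLE_RA/NON_RA).
#'
#' Validation is strict: unknown patient ids, dates outside the observation
#' window, unparseable dates, invalid enum values, duplicate or missing
#' labels, and hospital records whose diagnosis list exceeds the source
#' capacity (16 codes for ICD-9 abstracts, 25 for ICD-10) are load-time
#' errors, never silently dropped.
#'
#' @param patients,claims,hospital,drugs,labels Data frames with the columns
#'   above; event tables may be `NULL` for "no events".
#' @param obs_start,obs_end Observation window (Dates).
#' @param index_date Date at which age is computed.
#' @return An object of class `ra_cohort`.
#' @export
ra_cohort <- function(patients, claims = NULL, hospital = NULL, drugs = NULL,
                      labels = NULL,
                      obs_start = DEFAULT_OBS_START, obs_end = DEFAULT_OBS_END,
                      index_date = DEFAULT_INDEX_DATE) {
  obs_start <- as.Date(obs_start)
  obs_end <- as.Date(obs_end)
  index_date <- as.Date(index_date)
  stopifnot(obs_start <= obs_end)

  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  check_columns(patients, c("patient_id", "birth_date", "sex"), "patients")
  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in patients table")
  }
  patients$birth_date <- parse_iso_date(patients$birth_date, "patients$birth_date")
  check_enum(patients$sex, SEXES, "sex")
  patients$sex <- as.character(patients$sex)
  ids <- patients$patient_id

  claims <- if (is.null(claims) || !nrow(as.data.frame(claims))) empty_claims() else as.data.frame(claims, stringsAsFactors = FALSE)
  check_columns(claims, names(empty_claims()), "physician_claims")
  if (nrow(claims)) {
    claims$patient_id <- as.character(claims$patient_id)
    check_known_patients(claims$patient_id, ids, "physician_claims")
    claims$service_date <- parse_iso_date(claims$service_date, "physician_claims$service_date")
    check_window(claims$service_date, obs_start, obs_end, "physician_claims")
    check_enum(claims$dx_system, DX_SYSTEMS, "dx_system")
    if (any(is.na(claims$dx_code) | !nzchar(trimws(claims$dx_code)))) {
      stop("physician_claims: dx_code must be non-empty (exactly one diagnosis per claim)")
    }
    claims$dx_code <- as.character(claims$dx_code)
    claims$dx_system <- as.character(claims$dx_system)
    claims$specialty <- as.character(claims$specialty)
  }

  hospital <- if (is.null(hospital) || !nrow(as.data.frame(hospital))) empty_hospital() else as.data.frame(hospital, stringsAsFactors = FALSE)
  check_columns(hospital, names(empty_hospital()), "hospital_records")
  if (nrow(hospital)) {
    hospital$patient_id <- as.character(hospital$patient_id)
    check_known_patients(hospital$patient_id, ids, "hospital_records")
    hospital$event_date <- parse_iso_date(hospital$event_date, "hospital_records$event_date")
    check_window(hospital$event_date, obs_start, obs_end, "hospital_records")
    check_enum(hospital$setting, SETTINGS, "setting")
    check_enum(hospital$dx_system, c("ICD9", "ICD10"), "hospital dx_system")
    hospital$setting <- as.character(hospital$setting)
    hospital$dx_codes <- as.character(hospital$dx_codes)
    hospital$dx_system <- as.character(hospital$dx_system)
    ncodes <- lengths(strsplit(hospital$dx_codes, ";", fixed = TRUE))
    cap <- ifelse(hospital$dx_system == "ICD9", 16L, 25L)
    bad <- which(ncodes < 1L | ncodes > cap)
    if (length(bad)) {
      stop(
        "hospital_records: diagnosis list size out of range (1..16 ICD9, 1..25 ICD10) ",
        "at row(s) ", paste(utils::head(bad, 5L), collapse = ", ")
      )
    }
  }

  drugs <- if (is.null(drugs) || !nrow(as.data.frame(drugs))) empty_drugs() else as.data.frame(drugs, stringsAsFactors = FALSE)
  check_columns(drugs, names(empty_drugs()), "drug_claims")
  if (nrow(drugs)) {
    drugs$patient_id <- as.character(drugs$patient_id)
    check_known_patients(drugs$patient_id, ids, "drug_claims")
    drugs$dispense_date <- parse_iso_date(drugs$dispense_date, "drug_claims$dispense_date")
    check_window(drugs$dispense_date, obs_start, obs_end, "drug_claims")
    check_enum(drugs$drug_class, DRUG_CLASSES, "drug_class")
    drugs$drug_class <- as.character(drugs$drug_class)
  }

  if (!is.null(labels)) {
    labels <- as.data.frame(labels, stringsAsFactors = FALSE)
    check_columns(labels, c("patient_id", "status"), "labels")
    labels$patient_id <- as.character(labels$patient_id)
    check_enum(labels$status, LABEL_STATUSES, "label status")
    labels$status <- as.character(labels$status)
    if (anyDuplicated(labels$patient_id)) {
      stop("duplicate patient_id in labels")
    }
    check_known_patients(labels$patient_id, ids, "labels")
    unlabeled <- setdiff(ids, labels$patient_id)
    if (length(unlabeled)) {
      stop(
        "every patient must carry a reference label; missing for: ",
        paste(utils::head(unlabeled, 5L), collapse = ", "),
        if (length(unlabeled) > 5L) " ..." else ""
      )
    }
  } else {
    labels <- data.frame(patient_id = character(), status = character(),
                         stringsAsFactors = FALSE)
  }

  structure(
    list(
      patients = patients, claims = claims, hospital = hospital, drugs = drugs,
      labels = labels, obs_start = obs_start, obs_end = obs_end,
      index_date = index_date
    ),
    class = "ra_cohort"
  )
}

#' @export
print.ra_cohort <- function(x, ...) {
  cat("<ra_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$claims), " physician claims, ", nrow(x$hospital),
      " hospital/ER records, ", nrow(x$drugs), " drug claims\n", sep = "")
  cat("  observation window: ", format(x$obs_start), " .. ", format(x$obs_end),
      "; index date ", format(x$index_date), "\n", sep = "")
  if (nrow(x$labels)) {
    tab <- table(factor(x$labels$status, LABEL_STATUSES))
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Age in whole years at a date
#' @param birth_date,at Dates.
#' @return Integer vector of completed years.
#' @export
age_at <- function(birth_date, at = DEFAULT_INDEX_DATE) {
  birth_date <- as.Date(birth_date)
  at <- as.Date(at)
  b <- as.POSIXlt(birth_date)
  a <- as.POSIXlt(at)
  age <- a$year - b$year
  before_birthday <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  as.integer(age - before_birthday)
}

#' Single patient record
#'
#' Convenience constructor for one subject's event streams, used by the
#' per-patient engine operations and throughout the tests. Event tables take
#' the same columns as in [ra_cohort()] minus `patient_id`.
#'
#' @param patient_id Opaque identifier.
#' @param birth_date Birth date (Date or ISO string).
#' @param sex `"F"` or `"M"`.
#' @param claims,hospital,drugs Event data frames (or `NULL`).
#' @param obs_start,obs_end,index_date See [ra_cohort()].
#' @return An object of class `ra_patient`.
#' @export
patient_record <- function(patient_id, birth_date, sex = "F",
                           claims = NULL, hospital = NULL, drugs = NULL,
                           obs_start = DEFAULT_OBS_START,
                           obs_end = DEFAULT_OBS_END,
                           index_date = DEFAULT_INDEX_DATE) {
  add_id <- function(df, empty) {
    if (is.null(df) || !nrow(as.data.frame(df))) return(empty)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    df$patient_id <- patient_id
    df[, names(empty)]
  }
  cohort <- ra_cohort(
    patients = data.frame(patient_id = patient_id, birth_date = as.character(birth_date),
                          sex = sex, stringsAsFactors = FALSE),
    claims = add_id(claims, empty_claims()),
    hospital = add_id(hospital, empty_hospital()),
    drugs = add_id(drugs, empty_drugs()),
    labels = data.frame(patient_id = patient_id, status = "NON_RA",
                        stringsAsFactors = FALSE),
    obs_start = obs_start, obs_end = obs_end, index_date = index_date
  )
  structure(
    list(
      patient_id = patient_id, birth_date = as.Date(birth_date), sex = sex,
      claims = cohort$claims, hospital = cohort$hospital, drugs = cohort$drugs,
      obs_start = cohort$obs_start, obs_end = cohort$obs_end,
      index_date = cohort$index_date
    ),
    class = "ra_patient"
  )
}

#' Extract one patient's record from a cohort
#' @param cohort An `ra_cohort`.
#' @param patient_id Identifier present in the cohort.
#' @return An `ra_patient`.
#' @export
cohort_patient <- function(cohort, patient_id) {
  stopifnot(inherits(cohort, "ra_cohort"))
  row <- cohort$patients[cohort$patients$patient_id == patient_id, , drop = FALSE]
  if (!nrow(row)) stop("unknown patient_id: ", patient_id)
  structure(
    list(
      patient_id = patient_id, birth_date = row$birth_date, sex = row$sex,
      claims = cohort$claims[cohort$claims$patient_id == patient_id, , drop = FALSE],
      hospital = cohort$hospital[cohort$hospital$patient_id == patient_id, , drop = FALSE],
      drugs = cohort$drugs[cohort$drugs$patient_id == patient_id, , drop = FALSE],
      obs_start = cohort$obs_start, obs_end = cohort$obs_end,
      index_date = cohort$index_date
    ),
    class = "ra_patient"
  )
}

cohort_file_names <- c(
  patients = "patients.csv", claims = "physician_claims.csv",
  hospital = "hospital_records.csv", drugs = "drug_claims.csv",
  labels = "labels.csv"
)

#' Read a cohort from its five-CSV directory layout
#'
#' Expects `patients.csv`, `physician_claims.csv`, `hospital_records.csv`,
#' `drug_claims.csv` and `labels.csv` (UTF-8, header row) under `dir`;
#' individual paths can be overridden via `paths`. All dates must be ISO 8601.
#'
#' @param dir Directory containing the five CSV files.
#' @param paths Optional named character vector overriding individual file
#'   locations (names among `r toString(names(cohort_file_names))`).
#' @inheritParams ra_cohort
#' @return An `ra_cohort`.
#' @export
read_cohort <- function(dir = ".", paths = NULL,
                        obs_start = DEFAULT_OBS_START,
                        obs_end = DEFAULT_OBS_END,
                        index_date = DEFAULT_INDEX_DATE) {
  files <- file.path(dir, cohort_file_names)
  names(files) <- names(cohort_file_names)
  if (!is.null(paths)) files[names(paths)] <- paths
  absent <- files[!file.exists(files)]
  if (length(absent)) {
    stop("cohort file(s) not found: ", paste(absent, collapse = ", "))
  }
  rd <- function(f) {
    as.data.frame(data.table::fread(f, colClasses = "character", na.strings = NULL))
  }
  ra_cohort(
    patients = rd(files["patients"]),
    claims = rd(files["claims"]),
    hospital = rd(files["hospital"]),
    drugs = rd(files["drugs"]),
    labels = rd(files["labels"]),
    obs_start = obs_start, obs_end = obs_end, index_date = index_date
  )
}

#' Write a cohort to the five-CSV directory layout
#'
#' Output is deterministic (stable row order, ISO dates), so identical cohorts
#' produce byte-identical files.
#'
#' @param cohort An `ra_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ra_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, f, datecols) {
    df <- as.data.frame(df)
    for (dc in datecols) df[[dc]] <- format(df[[dc]], "%Y-%m-%d")
    ord <- do.call(order, unname(df))
    data.table::fwrite(df[ord, , drop = FALSE], f)
  }
  wr(cohort$patients, file.path(dir, "patients.csv"), "birth_date")
  wr(cohort$claims, file.path(dir, "physician_claims.csv"), "service_date")
  wr(cohort$hospital, file.path(dir, "hospital_records.csv"), "event_date")
  wr(cohort$drugs, file.path(dir, "drug_claims.csv"), "dispense_date")
  wr(cohort$labels, file.path(dir, "labels.csv"), character())
  invisible(dir)
}

#' Binarise reference labels
#'
#' Collapses the three-level chart-review label to case/non-case. Under
#' `DEFINITE_ONLY`, possible-RA patients count as non-cases (the primary
#' reference definition); under `DEFINITE_PLUS_POSSIBLE` they count as cases
#' (the sensitivity analysis that regroups definite and possible RA).
#'
#' @param labels Data frame with columns `patient_id`, `status`, or an
#'   `ra_cohort` (its `labels` table is used).
#' @param mode `"DEFINITE_ONLY"` or `"DEFINITE_PLUS_POSSIBLE"`.
#' @return Named logical vector: `TRUE` = case, names are patient ids.
#' @examples
#' labs <- data.frame(
#'   patient_id = c("A", "B", "C"),
#'   status = c("DEFINITE_RA", "POSSIBLE_RA", "NON_RA")
#' )
#' apply_reference_definition(labs, "DEFINITE_ONLY")
#' apply_reference_definition(labs, "DEFINITE_PLUS_POSSIBLE")
#' @export
apply_reference_definition <- function(labels,
                                       mode = c("DEFINITE_ONLY", "DEFINITE_PLUS_POSSIBLE")) {
  mode <- match.arg(mode)
  if (inherits(labels, "ra_cohort")) labels <- labels$labels
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  check_columns(labels, c("patient_id", "status"), "labels")
  if (anyDuplicated(labels$patient_id)) {
    stop("duplicate patient_id in labels: ",
         paste(unique(labels$patient_id[duplicated(labels$patient_id)]), collapse = ", "))
  }
  check_enum(labels$status, LABEL_STATUSES, "label status")
  case_statuses <- if (mode == "DEFINITE_ONLY") "DEFINITE_RA" else c("DEFINITE_RA", "POSSIBLE_RA")
  stats::setNames(labels$status %in% case_statuses, labels$patient_id)
}
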