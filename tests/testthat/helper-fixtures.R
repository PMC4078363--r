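# Shared fixtures: tiny hand-built patients, a random tiny-patient generator,
# and an independent brute-force oracle for algorithm evaluation.

D <- function(x) as.Date(x)

# physician claims data frame from day offsets relative to an epoch
claims_df <- function(days, code = "714", system = "OHIP_DX",
                      specialty = "family medicine",
                      epoch = as.Date("2000-01-01")) {
  data.frame(
    service_date = epoch + days,
    dx_code = rep_len(code, length(days)),
    dx_system = rep_len(system, length(days)),
    specialty = rep_len(specialty, length(days)),
    stringsAsFactors = FALSE
  )
}

hosp_df <- function(days, dx_codes = "714", setting = "INPATIENT",
                    system = "ICD9", epoch = as.Date("2000-01-01")) {
  data.frame(
    event_date = epoch + days,
    setting = rep_len(setting, length(days)),
    dx_codes = rep_len(dx_codes, length(days)),
    dx_system = rep_len(system, length(days)),
    stringsAsFactors = FALSE
  )
}

drugs_df <- function(days, class = "DMARD", epoch = as.Date("2000-01-01")) {
  data.frame(
    dispense_date = epoch + days,
    drug_class = rep_len(class, length(days)),
    stringsAsFactors = FALSE
  )
}

# a senior (77 y at the 2010-12-31 index date) unless told otherwise
tiny_patient <- function(claims = NULL, hospital = NULL, drugs = NULL,
                         birth_date = "1933-05-20", id = "pt1") {
  patient_record(id, birth_date,
                 claims = claims, hospital = hospital, drugs = drugs)
}

# in-memory labelled cohort from a list of ra_patient objects
patients_to_cohort <- function(patients, statuses) {
  stopifnot(length(patients) == length(statuses))
  grab <- function(field) {
    do.call(rbind, lapply(patients, function(p) {
      df <- p[[field]]
      if (nrow(df)) df else NULL
    }))
  }
  ra_cohort(
    patients = data.frame(
      patient_id = vapply(patients, `[[`, character(1), "patient_id"),
      birth_date = as.Date(vapply(patients, function(p) format(p$birth_date), character(1))),
      sex = "F", stringsAsFactors = FALSE
    ),
    claims = grab("claims"), hospital = grab("hospital"), drugs = grab("drugs"),
    labels = data.frame(
      patient_id = vapply(patients, `[[`, character(1), "patient_id"),
      status = statuses, stringsAsFactors = FALSE
    )
  )
}

# --------------------------------------------------------------------------
# random tiny patients (<= 12 events) exercising every engine feature

random_tiny_patient <- function(id) {
  n_claims <- sample(0:8, 1)
  n_hosp <- sample(0:2, 1)
  n_drugs <- sample(0:2, 1)
  epoch <- as.Date("1996-01-01")
  span <- 2200 # ~6 years, so 1-3 y windows bind
  claims <- if (n_claims) {
    data.frame(
      service_date = epoch + sample.int(span, n_claims, replace = TRUE),
      dx_code = sample(c("714", "714.0", "715", "250"), n_claims, replace = TRUE,
                       prob = c(0.4, 0.15, 0.25, 0.2)),
      dx_system = "OHIP_DX",
      specialty = sample(c("rheumatology", "orthopedic surgery", "family medicine"),
                         n_claims, replace = TRUE, prob = c(0.3, 0.1, 0.6)),
      stringsAsFactors = FALSE
    )
  }
  hospital <- if (n_hosp) {
    data.frame(
      event_date = epoch + sample.int(span, n_hosp, replace = TRUE),
      setting = sample(c("INPATIENT", "ER"), n_hosp, replace = TRUE),
      dx_codes = sample(c("714", "428;714", "428", "401;250"), n_hosp, replace = TRUE),
      dx_system = "ICD9",
      stringsAsFactors = FALSE
    )
  }
  drugs <- if (n_drugs) {
    data.frame(
      dispense_date = epoch + sample.int(span, n_drugs, replace = TRUE),
      drug_class = sample(c("DMARD", "GLUCOCORTICOSTEROID", "NSAID_COXIB"),
                          n_drugs, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  birth <- sample(c("1925-03-01", "1944-11-30", "1970-07-15"), 1) # 85, 66, 40 y
  patient_record(id, birth, claims = claims, hospital = hospital, drugs = drugs)
}

# --------------------------------------------------------------------------
# brute-force oracle: exhaustive enumeration of date subsets, written
# directly from the clause definition and kept independent of the engine's
# chain dynamic program

# low-level enumeration over all size-n date subsets; the decision logic of
# the oracle, shared by the per-patient and whole-cohort checkers
oracle_subset_ok <- function(d, sp, clause, rx) {
  n <- clause$n_codes
  if (length(d) < n) return(FALSE)
  if (clause$require_rx && !length(rx)) return(FALSE)
  subsets <- utils::combn(length(d), n, simplify = FALSE)
  for (idx in subsets) {
    sub <- d[idx] # ascending since d is
    if (is.finite(clause$window_days) &&
        (sub[n] - sub[1]) > clause$window_days) next
    if (n >= 2 && any(diff(sub) < clause$min_gap_days)) next
    if (clause$require_specialist && !any(sp[idx])) next
    if (clause$require_rx) {
      ok <- if (is.finite(clause$window_days)) {
        any(pmax(sub[n], rx) - pmin(sub[1], rx) <= clause$window_days)
      } else {
        TRUE # >= 1 claim of an accepted class exists, checked above
      }
      if (!ok) next
    }
    return(TRUE)
  }
  FALSE
}

oracle_clause <- function(clause, patient, config = default_code_config()) {
  age <- age_at(patient$birth_date, patient$index_date)
  if (clause$source == "PHYSICIAN") {
    qp <- qualifying_physician_dates(patient, config)
    d <- as.integer(qp$date)
    sp <- qp$specialist
  } else {
    setting <- if (clause$source == "HOSPITAL") "INPATIENT" else "ER"
    hs <- patient$hospital[patient$hospital$setting == setting, , drop = FALSE]
    d <- integer()
    if (nrow(hs)) {
      for (i in seq_len(nrow(hs))) {
        codes <- strsplit(hs$dx_codes[i], ";", fixed = TRUE)[[1]]
        if (any(classify_code(codes, hs$dx_system[i], config) == "RA")) {
          d <- c(d, as.integer(hs$event_date[i]))
        }
      }
      d <- sort(unique(d))
    }
    sp <- rep(FALSE, length(d))
  }
  rx <- integer()
  if (clause$require_rx) {
    if (age < 65) return(FALSE)
    keep <- patient$drugs$drug_class %in% clause$rx_classes
    rx <- as.integer(patient$drugs$dispense_date[keep])
  }
  oracle_subset_ok(d, sp, clause, rx)
}

oracle_exclusion <- function(patient, exclude_a, exclude_b,
                             config = default_code_config()) {
  cl <- patient$claims
  if (!nrow(cl)) return(FALSE)
  kind <- classify_code(cl$dx_code, cl$dx_system, config)
  ra_days <- as.integer(cl$service_date[kind == "RA"])
  if (!length(ra_days)) return(FALSE)
  trig <- FALSE
  if (exclude_a) {
    other <- as.integer(cl$service_date[kind == "OTHER_RHEUM"])
    trig <- trig || any(other > max(ra_days))
  }
  if (exclude_b) {
    is_rheum <- tolower(trimws(cl$specialty)) == "rheumatology"
    trig <- trig ||
      any(is_rheum & kind != "RA" & as.integer(cl$service_date) >= min(ra_days))
  }
  trig
}

# whole-cohort oracle check with per-patient precomputation: extracts each
# patient's qualifying/RA/drug dates once, then brute-force-enumerates every
# unique clause and combines per algorithm. Returns mismatching
# patient/algorithm pairs against `pred` (a matrix from evaluate_cohort).
oracle_check_cohort <- function(cohort, algs, pred,
                                config = default_code_config()) {
  ids <- rownames(pred)
  cls <- classify_code(cohort$claims$dx_code, cohort$claims$dx_system, config)
  is_ra <- cls == "RA"
  msk <- is_msk_specialist(cohort$claims$specialty, config)
  day <- as.integer(cohort$claims$service_date)
  pid <- cohort$claims$patient_id
  split_i <- split(seq_along(pid), pid)

  hosp <- cohort$hospital
  hosp_ra <- logical(nrow(hosp))
  if (nrow(hosp)) {
    for (i in seq_len(nrow(hosp))) {
      codes <- strsplit(hosp$dx_codes[i], ";", fixed = TRUE)[[1]]
      hosp_ra[i] <- any(classify_code(codes, hosp$dx_system[i], config) == "RA")
    }
  }
  hsplit <- split(seq_len(nrow(hosp)), hosp$patient_id)
  dsplit <- split(seq_len(nrow(cohort$drugs)), cohort$drugs$patient_id)
  ages <- stats::setNames(
    age_at(cohort$patients$birth_date, cohort$index_date),
    cohort$patients$patient_id
  )

  clause_key <- function(cl) render_algorithm(ra_algorithm("k", list(cl)))
  uclauses <- list()
  for (alg in algs) {
    for (cl in alg$clauses) uclauses[[clause_key(cl)]] <- cl
  }

  mism <- list()
  for (id in ids) {
    ci <- split_i[[id]]
    ra_i <- ci[is_ra[ci]]
    # distinct RA-coded days, specialist flag per day
    dmap <- sort(unique(day[ra_i]))
    spd <- vapply(dmap, function(dd) any(msk[ra_i][day[ra_i] == dd]), logical(1))
    hi <- hsplit[[id]]
    hosp_days <- sort(unique(as.integer(
      hosp$event_date[hi][hosp_ra[hi] & hosp$setting[hi] == "INPATIENT"]
    )))
    er_days <- sort(unique(as.integer(
      hosp$event_date[hi][hosp_ra[hi] & hosp$setting[hi] == "ER"]
    )))
    di <- dsplit[[id]]
    drug_day <- as.integer(cohort$drugs$dispense_date[di])
    drug_cls <- cohort$drugs$drug_class[di]
    age <- ages[[id]]

    cres <- vapply(uclauses, function(cl) {
      if (cl$require_rx && age < 65) return(FALSE)
      rx <- if (cl$require_rx) drug_day[drug_cls %in% cl$rx_classes] else integer()
      src <- switch(cl$source,
                    PHYSICIAN = list(dmap, spd),
                    HOSPITAL = list(hosp_days, rep(FALSE, length(hosp_days))),
                    ER = list(er_days, rep(FALSE, length(er_days))))
      oracle_subset_ok(src[[1]], src[[2]], cl, rx)
    }, logical(1))

    excl <- c(a = FALSE, b = FALSE)
    if (length(ra_i)) {
      other <- day[ci][cls[ci] == "OTHER_RHEUM"]
      excl["a"] <- any(other > max(day[ra_i]))
      rheum <- tolower(trimws(cohort$claims$specialty[ci])) == "rheumatology"
      excl["b"] <- any(rheum & cls[ci] != "RA" & day[ci] >= min(day[ra_i]))
    }

    for (alg in algs) {
      want <- if (!is.null(alg$age_subset) && age < alg$age_subset) {
        FALSE
      } else {
        pos <- any(vapply(alg$clauses, function(cl) cres[[clause_key(cl)]],
                          logical(1)))
        pos &&
          !((alg$exclude_a && excl[["a"]]) || (alg$exclude_b && excl[["b"]]))
      }
      if (!identical(unname(want), unname(pred[id, alg$algorithm_id]))) {
        mism[[length(mism) + 1L]] <- c(id, alg$algorithm_id)
      }
    }
  }
  mism
}

# vectorized random tiny-event cohort (same event distribution as
# random_tiny_patient) for large-scale oracle comparisons
random_tiny_cohort <- function(n) {
  nc <- sample(0:8, n, TRUE)
  nh <- sample(0:2, n, TRUE)
  nd <- sample(0:2, n, TRUE)
  ids <- sprintf("r%05d", seq_len(n))
  epoch <- as.Date("1996-01-01")
  claims <- if (sum(nc)) data.frame(
    patient_id = rep(ids, nc),
    service_date = epoch + sample.int(2200, sum(nc), TRUE),
    dx_code = sample(c("714", "714.0", "715", "250"), sum(nc), TRUE,
                     prob = c(0.4, 0.15, 0.25, 0.2)),
    dx_system = "OHIP_DX",
    specialty = sample(c("rheumatology", "orthopedic surgery", "family medicine"),
                       sum(nc), TRUE, prob = c(0.3, 0.1, 0.6)),
    stringsAsFactors = FALSE
  )
  hosp <- if (sum(nh)) data.frame(
    patient_id = rep(ids, nh),
    event_date = epoch + sample.int(2200, sum(nh), TRUE),
    setting = sample(c("INPATIENT", "ER"), sum(nh), TRUE),
    dx_codes = sample(c("714", "428;714", "428", "401;250"), sum(nh), TRUE),
    dx_system = "ICD9",
    stringsAsFactors = FALSE
  )
  drugs <- if (sum(nd)) data.frame(
    patient_id = rep(ids, nd),
    dispense_date = epoch + sample.int(2200, sum(nd), TRUE),
    drug_class = sample(c("DMARD", "GLUCOCORTICOSTEROID", "NSAID_COXIB"),
                        sum(nd), TRUE),
    stringsAsFactors = FALSE
  )
  ra_cohort(
    patients = data.frame(
      patient_id = ids,
      birth_date = sample(c("1925-03-01", "1944-11-30", "1970-07-15"), n, TRUE),
      sex = "F", stringsAsFactors = FALSE
    ),
    claims = claims, hospital = hosp, drugs = drugs,
    labels = data.frame(patient_id = ids, status = "NON_RA",
                        stringsAsFactors = FALSE)
  )
}

oracle_evaluate <- function(alg, patient, config = default_code_config()) {
  age <- age_at(patient$birth_date, patient$index_date)
  if (!is.null(alg$age_subset) && age < alg$age_subset) return(FALSE)
  pos <- any(vapply(alg$clauses, oracle_clause, logical(1),
                    patient = patient, config = config))
  if (!pos) return(FALSE)
  if ((alg$exclude_a || alg$exclude_b) &&
      oracle_exclusion(patient, alg$exclude_a, alg$exclude_b, config)) {
    return(FALSE)
  }
  TRUE
}
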