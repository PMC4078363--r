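make_small_cohort <- function() {
  ra_cohort(
    patients = data.frame(
      patient_id = c("A", "B"),
      birth_date = c("1950-02-10", "1988-09-01"),
      sex = c("F", "M"), stringsAsFactors = FALSE
    ),
    claims = data.frame(
      patient_id = c("A", "A", "B"),
      service_date = c("2001-05-01", "2002-06-01", "2003-01-15"),
      dx_code = c("714", "714", "250"), dx_system = "OHIP_DX",
      specialty = c("rheumatology", "family medicine", "family medicine"),
      stringsAsFactors = FALSE
    ),
    hospital = data.frame(
      patient_id = "A", event_date = "2005-03-03", setting = "INPATIENT",
      dx_codes = "M05.9;I10", dx_system = "ICD10", stringsAsFactors = FALSE
    ),
    drugs = data.frame(
      patient_id = "A", dispense_date = "2001-06-01", drug_class = "DMARD",
      stringsAsFactors = FALSE
    ),
    labels = data.frame(
      patient_id = c("A", "B"), status = c("DEFINITE_RA", "NON_RA"),
      stringsAsFactors = FALSE
    )
  )
}

test_that("rows map to patients; empty event tables are fine", {
  coh <- make_small_cohort()
  expect_identical(sort(table(coh$claims$patient_id), decreasing = TRUE),
                   sort(table(c("A", "A", "B")), decreasing = TRUE))
  lone <- ra_cohort(
    patients = data.frame(patient_id = "Z", birth_date = "1960-01-01", sex = "M"),
    labels = data.frame(patient_id = "Z", status = "NON_RA")
  )
  expect_identical(nrow(lone$claims), 0L)
  expect_identical(nrow(lone$hospital), 0L)
})

test_that("validation errors name the offence", {
  pats <- data.frame(patient_id = "A", birth_date = "1950-02-10", sex = "F")
  labs <- data.frame(patient_id = "A", status = "NON_RA")
  # event before the observation window start
  expect_error(
    ra_cohort(pats, claims = data.frame(
      patient_id = "A", service_date = "1989-01-01", dx_code = "714",
      dx_system = "OHIP_DX", specialty = "gp"
    ), labels = labs),
    "outside observation window"
  )
  expect_error(
    ra_cohort(pats, claims = data.frame(
      patient_id = "A", service_date = "not-a-date", dx_code = "714",
      dx_system = "OHIP_DX", specialty = "gp"
    ), labels = labs),
    "unparseable ISO 8601"
  )
  expect_error(
    ra_cohort(pats, claims = data.frame(
      patient_id = "GHOST", service_date = "2001-01-01", dx_code = "714",
      dx_system = "OHIP_DX", specialty = "gp"
    ), labels = labs),
    "unknown patient_id"
  )
  expect_error(
    ra_cohort(pats, claims = data.frame(
      patient_id = "A", service_date = "2001-01-01", dx_code = "714",
      dx_system = "OHIP_DX"
    ), labels = labs),
    "missing required column.*specialty"
  )
  expect_error(
    ra_cohort(pats, labels = data.frame(patient_id = "A", status = "MAYBE_RA")),
    "invalid label status"
  )
  expect_error(
    ra_cohort(pats, labels = data.frame(patient_id = c("A", "A"),
                                        status = c("NON_RA", "NON_RA"))),
    "duplicate patient_id"
  )
  expect_error(
    ra_cohort(pats,
              hospital = data.frame(
                patient_id = "A", event_date = "2003-01-01", setting = "INPATIENT",
                dx_codes = paste(rep("401", 20), collapse = ";"), dx_system = "ICD9"
              ),
              labels = labs),
    "diagnosis list size"
  )
})

test_that("cohorts survive the CSV round trip with the event multiset intact", {
  coh <- make_small_cohort()
  dir <- file.path(tempdir(), "coh_rt")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  key <- function(df) {
    if (!nrow(df)) return(character())
    sort(do.call(paste, c(lapply(df, as.character), sep = "|")))
  }
  for (tab in c("patients", "claims", "hospital", "drugs", "labels")) {
    expect_identical(key(back[[tab]]), key(coh[[tab]]), label = tab)
  }
  expect_error(read_cohort(file.path(tempdir(), "no_such_dir")), "not found")
})

test_that("reference definition modes binarise labels as defined", {
  labs <- data.frame(
    patient_id = c("A", "B", "C"),
    status = c("DEFINITE_RA", "POSSIBLE_RA", "NON_RA")
  )
  expect_identical(apply_reference_definition(labs, "DEFINITE_ONLY"),
                   c(A = TRUE, B = FALSE, C = FALSE))
  expect_identical(apply_reference_definition(labs, "DEFINITE_PLUS_POSSIBLE"),
                   c(A = TRUE, B = TRUE, C = FALSE))
  allnon <- data.frame(patient_id = c("X", "Y"), status = "NON_RA")
  expect_false(any(apply_reference_definition(allnon, "DEFINITE_ONLY")))
  expect_false(any(apply_reference_definition(allnon, "DEFINITE_PLUS_POSSIBLE")))
  expect_error(
    apply_reference_definition(
      data.frame(patient_id = c("A", "A"), status = "NON_RA"), "DEFINITE_ONLY"
    ),
    "duplicate"
  )
})

test_that("regrouping possible RA can only grow the case set", {
  set.seed(421)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    labs <- data.frame(
      patient_id = sprintf("p%02d", seq_len(n)),
      status = sample(c("DEFINITE_RA", "POSSIBLE_RA", "NON_RA"), n, replace = TRUE)
    )
    a <- apply_reference_definition(labs, "DEFINITE_ONLY")
    b <- apply_reference_definition(labs, "DEFINITE_PLUS_POSSIBLE")
    expect_true(all(b[a])) # every definite-only case stays a case
    expect_gte(sum(b), sum(a))
    # partition: everyone is exactly one of case / non-case under either mode
    expect_identical(sort(names(a)), sort(labs$patient_id))
    expect_false(any(is.na(a)) || any(is.na(b)))
  }
})

test_that("age is computed in completed years at the index date", {
  expect_identical(age_at("1945-12-31", "2010-12-31"), 65L)
  expect_identical(age_at("1946-01-01", "2010-12-31"), 64L)
  expect_identical(age_at(c("1990-12-31", "1991-01-01"), "2010-12-31"), c(20L, 19L))
})
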