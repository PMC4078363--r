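test_that("the grammar parses and renders canonically", {
  a <- parse_algorithm("3P(spec>=1)/2y")
  cl <- a$clauses[[1]]
  expect_identical(cl$source, "PHYSICIAN")
  expect_identical(cl$n_codes, 3L)
  expect_identical(cl$window_days, 730L)
  expect_true(cl$require_specialist)
  expect_false(cl$require_rx)

  h <- parse_algorithm("1H")
  expect_identical(h$clauses[[1]]$source, "HOSPITAL")
  expect_identical(h$clauses[[1]]$n_codes, 1L)
  expect_identical(h$clauses[[1]]$window_days, Inf)

  two <- parse_algorithm("2P/1y | 2P/2y") # OR of clauses is legal, not an error
  expect_length(two$clauses, 2)

  ex <- parse_algorithm("1H | 2P(gap>=56d)/2y excl(A,B)")
  expect_true(ex$exclude_a)
  expect_true(ex$exclude_b)
  expect_identical(ex$clauses[[2]]$min_gap_days, 56L)

  for (t in c("1H", "1ER", "2P(gap>=60d,rx>=1)", "1H | 3P(spec>=1,rx>=1)/3y",
              "2P/400d", "1H | 2P(gap>=56d)/5y excl(A)")) {
    expect_identical(render_algorithm(parse_algorithm(t)), t, label = t)
  }
})

test_that("every packaged published algorithm round-trips through the grammar", {
  pub <- published_algorithm_results()
  algs <- default_algorithms()
  expect_length(algs, nrow(pub))
  for (i in seq_len(nrow(pub))) {
    expect_identical(render_algorithm(algs[[pub$algorithm_id[i]]]), pub$dsl[i])
  }
  expect_identical(
    sum(vapply(algs, function(a) identical(a$age_subset, 65L), TRUE)), 15L
  )
})

test_that("grammar errors are reported with the offending clause", {
  expect_error(parse_algorithm("0P/1y"), "n must be >= 1")
  expect_error(parse_algorithm("2X/1y"), "cannot parse clause")
  expect_error(parse_algorithm("2P(foo>=1)/1y"), "unknown option")
  expect_error(parse_algorithm("2P/1y excl(C)"), "unknown exclusion flag")
  expect_error(parse_algorithm("2P/1y | "), "empty clause")
})

test_that("qualifying physician dates deduplicate, filter and sort", {
  p <- tiny_patient(claims = rbind(
    claims_df(0, specialty = "family medicine"),
    claims_df(0, specialty = "rheumatology"), # same day, one specialist
    claims_df(100, code = "250"),
    claims_df(50)
  ))
  qp <- qualifying_physician_dates(p)
  expect_identical(nrow(qp), 2L) # day 0 (deduped) and day 50; 250 filtered
  expect_identical(qp$specialist, c(TRUE, FALSE))
  expect_true(!is.unsorted(qp$date))

  # count_same_day keeps both same-day claims
  expect_identical(nrow(qualifying_physician_dates(p, count_same_day = TRUE)), 3L)

  mixed <- tiny_patient(claims = claims_df(c(0, 10, 20), code = c("714", "250", "714")))
  expect_identical(nrow(qualifying_physician_dates(mixed)), 2L)
  expect_identical(nrow(qualifying_physician_dates(tiny_patient())), 0L)
})

test_that("hospital RA detection honours position, setting and coding era", {
  p <- tiny_patient(hospital = hosp_df(0, dx_codes = "428;714"))
  expect_true(hospital_ra_ever(p, "INPATIENT")) # secondary position counts
  expect_false(hospital_ra_ever(p, "ER"))
  er <- tiny_patient(hospital = hosp_df(1500, dx_codes = "M06.4", setting = "ER",
                                        system = "ICD10"))
  expect_true(hospital_ra_ever(er, "ER"))
  expect_false(hospital_ra_ever(er, "INPATIENT"))
  expect_false(hospital_ra_ever(tiny_patient(), "INPATIENT"))
})

test_that("window_satisfied matches its brute-force-derived examples", {
  epoch <- as.Date("2000-01-01")
  # all 3-subsets of {0,300,400}: only the full set spans <= 730, ends day 400
  expect_identical(window_satisfied(epoch + c(0, 300, 400), 3, 730), epoch + 400)
  # the only 2-subset of {0,30} violates the 56-day gap
  expect_true(is.na(window_satisfied(epoch + c(0, 30), 2, 730, min_gap_days = 56)))
  expect_true(is.na(window_satisfied(as.Date(character()), 1)))
  expect_error(window_satisfied(epoch, 0), "n must be >= 1")
  expect_warning(window_satisfied(epoch + c(0, 60, 120), 3, 100, min_gap_days = 60),
                 "unsatisfiable")
  expect_error(window_satisfied(epoch + c(5, 0), 1), "ascending")
  # earliest qualification: {0, 10, 400} with n=2, window 30 -> day 10
  expect_identical(window_satisfied(epoch + c(0, 10, 400), 2, 30), epoch + 10)
  # specialist must be among the counted dates
  expect_true(is.na(window_satisfied(epoch + c(0, 10, 500), 2, 30,
                                     require_specialist = TRUE,
                                     specialist = c(FALSE, FALSE, TRUE))))
  expect_identical(
    window_satisfied(epoch + c(0, 10, 500), 2, 30, require_specialist = TRUE,
                     specialist = c(TRUE, FALSE, TRUE)),
    epoch + 10
  )
})

test_that("drug co-requirement spans one window with the counted claims", {
  cl <- ra_clause("PHYSICIAN", 2, window_days = 365, require_rx = TRUE)
  # DMARD at day 100, claims at 50 and 200: all three span 150 <= 365
  p <- tiny_patient(claims = claims_df(c(50, 200)), drugs = drugs_df(100))
  expect_true(rx_satisfied(p, cl))
  # claims fit the window but no drug claim lands within reach
  far <- tiny_patient(claims = claims_df(c(50, 200)), drugs = drugs_df(1500))
  expect_false(rx_satisfied(far, cl))
  # drug class outside rx_classes never qualifies
  nsaid <- tiny_patient(claims = claims_df(c(50, 200)),
                        drugs = drugs_df(100, class = "NSAID_COXIB"))
  expect_false(rx_satisfied(nsaid, cl))
  # under-65 patients fail the clause outright (no pharmacy observation)
  young <- patient_record("y", "1970-07-15",
                          claims = claims_df(c(50, 200)), drugs = drugs_df(100))
  expect_false(rx_satisfied(young, cl))
  # "ever" clause: drug anywhere in the observation window
  ever <- ra_clause("PHYSICIAN", 1, require_rx = TRUE)
  expect_true(rx_satisfied(far, ever))
})

test_that("exclusion cases anchor on the last/first RA claim", {
  cfg <- default_code_config()
  # osteoarthritis after the last RA claim triggers Case A
  a_yes <- tiny_patient(claims = rbind(claims_df(c(0, 100)), claims_df(200, code = "715")))
  expect_true(exclusion_triggered(a_yes, exclude_a = TRUE, exclude_b = FALSE, config = cfg))
  # ... but not when it precedes the last RA claim
  a_no <- tiny_patient(claims = rbind(claims_df(c(0, 200)), claims_df(100, code = "715")))
  expect_false(exclusion_triggered(a_no, exclude_a = TRUE, exclude_b = FALSE, config = cfg))
  # both flags off: never triggers
  expect_false(exclusion_triggered(a_yes, exclude_a = FALSE, exclude_b = FALSE, config = cfg))
  # Case B: rheumatologist visit without an RA code on/after the first RA claim
  b_yes <- tiny_patient(claims = rbind(
    claims_df(0),
    claims_df(50, code = "250", specialty = "rheumatology")
  ))
  expect_true(exclusion_triggered(b_yes, exclude_a = FALSE, exclude_b = TRUE, config = cfg))
  b_no <- tiny_patient(claims = rbind(
    claims_df(50),
    claims_df(0, code = "250", specialty = "rheumatology") # before first RA
  ))
  expect_false(exclusion_triggered(b_no, exclude_a = FALSE, exclude_b = TRUE, config = cfg))
  # no RA billing at all: nothing to anchor on
  none <- tiny_patient(claims = claims_df(10, code = "715"))
  expect_false(exclusion_triggered(none, exclude_a = TRUE, exclude_b = TRUE, config = cfg))
})

test_that("evaluate_algorithm combines clauses and exclusions as specified", {
  opt <- parse_algorithm("1H | 3P(spec>=1)/2y")
  hosp_only <- tiny_patient(hospital = hosp_df(0, dx_codes = "428;714"))
  expect_true(evaluate_algorithm(opt, hosp_only)) # hospital branch alone

  threep <- tiny_patient(claims = claims_df(c(0, 40, 100))) # no specialist
  expect_false(evaluate_algorithm(parse_algorithm("3P(spec>=1)/1y"), threep))
  expect_true(evaluate_algorithm(parse_algorithm("3P/1y"), threep))

  empty <- tiny_patient()
  for (alg in default_algorithms()) {
    expect_false(evaluate_algorithm(alg, empty), label = alg$algorithm_id)
  }
})

test_that("engine agrees with exhaustive subset enumeration on random patients", {
  set.seed(4242)
  algs <- default_algorithms()
  for (i in 1:150) {
    p <- random_tiny_patient(sprintf("r%03d", i))
    for (alg in algs) {
      got <- evaluate_algorithm(alg, p)
      want <- oracle_evaluate(alg, p)
      if (!identical(got, want)) {
        fail(sprintf("patient %d disagrees on %s (engine %s, oracle %s)",
                     i, alg$algorithm_id, got, want))
      }
    }
  }
  succeed()
})

test_that("classification is invariant to date translation and event order", {
  set.seed(77)
  algs <- default_algorithms()[c("p1", "p2_1y", "p3_spec_2y", "h1_p2_gap8w_2y_exAB",
                                 "h1_p3_spec_rx_2y")]
  for (i in 1:25) {
    p <- random_tiny_patient(sprintf("t%02d", i))
    shift <- sample(c(-200L, 150L, 365L), 1)
    shifted <- p
    if (nrow(shifted$claims)) shifted$claims$service_date <- shifted$claims$service_date + shift
    if (nrow(shifted$hospital)) shifted$hospital$event_date <- shifted$hospital$event_date + shift
    if (nrow(shifted$drugs)) shifted$drugs$dispense_date <- shifted$drugs$dispense_date + shift
    scrambled <- p
    if (nrow(scrambled$claims) > 1) {
      scrambled$claims <- scrambled$claims[sample(nrow(scrambled$claims)), ]
    }
    for (alg in algs) {
      expect_identical(evaluate_algorithm(alg, shifted), evaluate_algorithm(alg, p),
                       label = paste("shift", alg$algorithm_id))
      expect_identical(evaluate_algorithm(alg, scrambled), evaluate_algorithm(alg, p),
                       label = paste("order", alg$algorithm_id))
    }
  }
})

test_that("longer windows can only add positives", {
  set.seed(99)
  w1 <- parse_algorithm("3P/1y")
  w2 <- parse_algorithm("3P/2y")
  for (i in 1:40) {
    p <- random_tiny_patient(sprintf("w%02d", i))
    expect_true(!evaluate_algorithm(w1, p) || evaluate_algorithm(w2, p))
  }
})

test_that("evaluate_cohort matches per-patient evaluation", {
  set.seed(31)
  pts <- lapply(1:40, function(i) random_tiny_patient(sprintf("c%02d", i)))
  coh <- patients_to_cohort(pts, sample(c("DEFINITE_RA", "NON_RA"), 40, replace = TRUE))
  algs <- default_algorithms()
  pred <- evaluate_cohort(coh, algs, subset = "all")
  for (i in c(1, 7, 19, 33)) {
    p <- pts[[i]]
    for (alg in algs) {
      expect_identical(unname(pred[p$patient_id, alg$algorithm_id]),
                       evaluate_algorithm(alg, p),
                       label = paste(p$patient_id, alg$algorithm_id))
    }
  }
})
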