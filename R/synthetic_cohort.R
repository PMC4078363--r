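# Seeded synthetic-cohort generator.
#
# Emulates an Ontario primary-care validation cohort: a stratified random
# sample of adults (>= 20 y at the index date) plus extra seniors (>= 65 y),
# reference-labelled by a chart review, linked to 20 years of administrative
# events. RA cases carry an active-care episode of frequent RA-coded billing
# (mostly specialist-involved), sometimes an RA-coded hospitalization, and —
# for seniors, whose pharmacy claims are observed — RA drug claims. Non-cases
# carry background billing with occasional RA miscodes. The marginal rates
# are the published ones where printed (drug exposures, specialist
# involvement, prevalence) and are otherwise calibrated to the printed
# confusion cells (coded fractions); visit-rate and episode-shape parameters
# have no published counterpart and are documented defaults.

#' Parameters of the synthetic cohort generator
#'
#' Defaults state the emulated world: cohort sizes 7500 adults + 2000 extra
#' seniors; lifetime RA prevalence 0.9% (ages 20-64) and 1.8% (65+); an extra
#' 0.4% of "possible RA" labels; 86% of cases with specialist-involved care;
#' 90% of cases ever RA-coded in billing (62/69); 3.3% of non-cases ever
#' miscoded (243/7431); 22% of cases with an RA-coded hospitalization
#' (15/69); senior-case drug exposure DMARD 80%, glucocorticosteroid 61%,
#' biologic 17%, NSAID/coxib 77%; 64% of cases female.
#'
#' @param n_adults,n_seniors_extra Sampled patients aged >= 20 / extra >= 65.
#' @param prev_adult,prev_senior Lifetime RA prevalence by age stratum
#'   (< 65 / >= 65 at the index date).
#' @param possible_ra_fraction Fraction of non-cases labelled "possible RA"
#'   (weakly documented charts), lifting combined prevalence to ~1.3%.
#' @param p_specialist_care P(case's RA billing involves an MSK specialist).
#' @param visit_rate_case Mean RA-coded visits/year during active care.
#' @param p_case_ever_coded P(case has >= 1 RA billing code).
#' @param p_case_minimal_coded P(coded case has exactly one RA code ever) —
#'   lifetime diagnoses no longer under care.
#' @param p_noncase_ever_coded P(non-case ever receives an RA miscode).
#' @param p_case_hosp,p_case_er P(case has an RA-coded inpatient / ER record).
#' @param p_noncase_hosp_ra,p_noncase_er_ra Same for non-cases (miscoding).
#' @param drug_probs_case Named exposure probabilities for senior cases
#'   (`DMARD`, `GLUCOCORTICOSTEROID`, `BIOLOGIC`, `NSAID_COXIB`).
#' @param drug_probs_noncase Same for senior non-cases.
#' @param p_female_case P(case is female); non-cases are 50/50.
#' @param p_msk_miscode P(a miscoded claim carries an MSK specialty).
#' @param bg_visit_rate Background (non-RA) visits/year for everyone.
#' @param active_years_range Active-care episode duration range (years).
#' @param p_quiescent_code P(case gets one late RA code after active care).
#' @param age_mean,age_sd,age_range Adult age distribution at the index date
#'   (truncated normal).
#' @param senior_age_mean,senior_age_sd Extra-senior age distribution.
#' @param obs_start,obs_end,index_date See [ra_cohort()].
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A validated list of class `ra_cohort_params`.
#' @export
cohort_params <- function(n_adults = 7500L,
                          n_seniors_extra = 2000L,
                          prev_adult = 0.009,
                          prev_senior = 0.018,
                          possible_ra_fraction = 0.004,
                          p_specialist_care = 0.86,
                          visit_rate_case = 4,
                          p_case_ever_coded = 0.90,
                          p_case_minimal_coded = 0.07,
                          p_noncase_ever_coded = 0.033,
                          p_case_hosp = 0.22,
                          p_case_er = 0.03,
                          p_noncase_hosp_ra = 0.0003,
                          p_noncase_er_ra = 0.0005,
                          drug_probs_case = c(DMARD = 0.80, GLUCOCORTICOSTEROID = 0.61,
                                              BIOLOGIC = 0.17, NSAID_COXIB = 0.77),
                          drug_probs_noncase = c(DMARD = 0.02, GLUCOCORTICOSTEROID = 0.20,
                                                 BIOLOGIC = 0.002, NSAID_COXIB = 0.40),
                          p_female_case = 0.64,
                          p_msk_miscode = 0.20,
                          bg_visit_rate = 1.0,
                          active_years_range = c(2, 8),
                          p_quiescent_code = 0.30,
                          age_mean = 49, age_sd = 17, age_range = c(20, 98),
                          senior_age_mean = 76.3, senior_age_sd = 6.8,
                          obs_start = DEFAULT_OBS_START,
                          obs_end = DEFAULT_OBS_END,
                          index_date = DEFAULT_INDEX_DATE,
                          seed = 1L) {
  p <- as.list(environment())
  probs <- c(
    prev_adult = prev_adult, prev_senior = prev_senior,
    possible_ra_fraction = possible_ra_fraction,
    p_specialist_care = p_specialist_care,
    p_case_ever_coded = p_case_ever_coded,
    p_case_minimal_coded = p_case_minimal_coded,
    p_noncase_ever_coded = p_noncase_ever_coded,
    p_case_hosp = p_case_hosp, p_case_er = p_case_er,
    p_noncase_hosp_ra = p_noncase_hosp_ra, p_noncase_er_ra = p_noncase_er_ra,
    p_female_case = p_female_case, p_msk_miscode = p_msk_miscode,
    p_quiescent_code = p_quiescent_code,
    drug_probs_case, drug_probs_noncase
  )
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probability parameters must be in [0, 1]")
  }
  if (p$n_adults < 1L) stop("n_adults must be >= 1")
  if (p$n_seniors_extra < 0L) stop("n_seniors_extra must be >= 0")
  if (p$visit_rate_case <= 0 || p$bg_visit_rate < 0) {
    stop("visit rates must be positive")
  }
  structure(p, class = "ra_cohort_params")
}

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

runif_days <- function(n, from, to) {
  # uniform whole-day dates in [from, to]
  from + floor(stats::runif(n) * (as.numeric(to - from) + 1))
}

ra_phys_code <- function(n) rep("714", n)

bg_code_pool <- data.frame(
  code = c("401", "250", "460", "780", "715", "724"),
  # hypertension, diabetes, URI, general symptoms, osteoarthritis, back pain
  w = c(0.28, 0.15, 0.22, 0.21, 0.04, 0.10),
  stringsAsFactors = FALSE
)

hosp_other_codes <- function(n, icd10) {
  if (icd10) sample(c("I10", "E11", "J18", "N39"), n, replace = TRUE)
  else sample(c("401", "250", "486", "599"), n, replace = TRUE)
}

#' Generate a synthetic reference-labelled cohort
#'
#' Deterministic given `params$seed`; the caller's RNG stream is left
#' untouched. All events fall inside the observation window.
#'
#' @param params An `ra_cohort_params`, see [cohort_params()].
#' @return An [ra_cohort()] whose `labels` table carries the reference
#'   standard.
#' @examples
#' coh <- generate_cohort(cohort_params(n_adults = 200, n_seniors_extra = 0, seed = 7))
#' table(coh$labels$status)
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "ra_cohort_params"))
  with_seed(params$seed, generate_cohort_impl(params))
}

generate_cohort_impl <- function(p) {
  n <- p$n_adults + p$n_seniors_extra
  ids <- sprintf("S%06d", seq_len(n))
  age <- c(
    rtrunc_norm(p$n_adults, p$age_mean, p$age_sd, p$age_range[1], p$age_range[2]),
    if (p$n_seniors_extra > 0)
      rtrunc_norm(p$n_seniors_extra, p$senior_age_mean, p$senior_age_sd, 65, 105)
  )
  birth <- p$index_date - floor(age * 365.25) - sample.int(365L, n, replace = TRUE) + 1L
  # exact integer age at index varies within +-1 y of `age`; recompute
  age_idx <- age_at(birth, p$index_date)
  is_senior <- age_idx >= 65L

  is_case <- stats::runif(n) < ifelse(is_senior, p$prev_senior, p$prev_adult)
  is_possible <- !is_case & stats::runif(n) < p$possible_ra_fraction
  status <- ifelse(is_case, "DEFINITE_RA", ifelse(is_possible, "POSSIBLE_RA", "NON_RA"))
  sex <- ifelse(
    stats::runif(n) < ifelse(is_case, p$p_female_case, 0.5), "F", "M"
  )

  win_days <- as.numeric(p$obs_end - p$obs_start) + 1
  win_years <- win_days / 365.25
  claims <- list()
  hospital <- list()
  drugs <- list()

  ## ---- background billing for everyone (never RA-coded)
  nbg <- stats::rpois(n, p$bg_visit_rate * win_years)
  tot <- sum(nbg)
  if (tot) {
    pid <- rep(ids, nbg)
    code <- sample(bg_code_pool$code, tot, replace = TRUE, prob = bg_code_pool$w)
    spec <- sample(c("family medicine", "rheumatology"), tot, replace = TRUE,
                   prob = c(0.995, 0.005))
    claims$bg <- data.frame(
      patient_id = pid,
      service_date = runif_days(tot, p$obs_start, p$obs_end),
      dx_code = code, dx_system = "OHIP_DX", specialty = spec,
      stringsAsFactors = FALSE
    )
  }

  ## ---- case RA billing streams
  ci <- which(is_case)
  if (length(ci)) {
    coded <- stats::runif(length(ci)) < p$p_case_ever_coded
    minimal <- coded & stats::runif(length(ci)) < p$p_case_minimal_coded
    spec_care <- stats::runif(length(ci)) < p$p_specialist_care
    # active-care episode: onset anywhere that leaves >= 1 y of follow-up
    onset <- runif_days(length(ci), p$obs_start, p$obs_end - 365L)
    dur_y <- stats::runif(length(ci), p$active_years_range[1], p$active_years_range[2])
    act_end <- pmin(onset + floor(dur_y * 365.25), p$obs_end)

    case_rows <- vector("list", length(ci))
    for (k in seq_along(ci)) {
      if (!coded[k]) next
      id <- ids[ci[k]]
      if (minimal[k]) {
        dts <- runif_days(1L, onset[k], act_end[k])
      } else {
        span_y <- as.numeric(act_end[k] - onset[k]) / 365.25
        nv <- max(2L, stats::rpois(1L, p$visit_rate_case * span_y))
        dts <- runif_days(nv, onset[k], act_end[k])
        if (stats::runif(1) < p$p_quiescent_code && act_end[k] < p$obs_end) {
          dts <- c(dts, runif_days(1L, act_end[k], p$obs_end))
        }
      }
      nv <- length(dts)
      if (spec_care[k]) {
        msk <- stats::runif(nv) < 0.5
        if (!any(msk)) msk[sample.int(nv, 1L)] <- TRUE
        specialty <- ifelse(
          msk,
          sample(c("rheumatology", "orthopedic surgery", "internal medicine"),
                 nv, replace = TRUE, prob = c(0.7, 0.15, 0.15)),
          "family medicine"
        )
      } else {
        specialty <- rep("family medicine", nv)
      }
      case_rows[[k]] <- data.frame(
        patient_id = id, service_date = sort(dts),
        dx_code = ra_phys_code(nv), dx_system = "OHIP_DX",
        specialty = specialty, stringsAsFactors = FALSE
      )
    }
    claims$case <- do.call(rbind, case_rows[!vapply(case_rows, is.null, TRUE)])

    ## RA-coded hospital / ER records
    hosp_i <- ci[stats::runif(length(ci)) < p$p_case_hosp]
    er_i <- ci[stats::runif(length(ci)) < p$p_case_er]
    mk_hosp <- function(idx, setting) {
      if (!length(idx)) return(NULL)
      dt <- runif_days(length(idx), p$obs_start, p$obs_end)
      icd10 <- dt >= as.Date("2002-01-01")
      ra <- ifelse(icd10, sample(c("M05.9", "M06.9"), length(idx), replace = TRUE), "714")
      dx <- vapply(seq_along(idx), function(j) {
        others <- hosp_other_codes(sample.int(3L, 1L), icd10[j])
        paste(sample(c(ra[j], others)), collapse = ";")
      }, character(1))
      data.frame(
        patient_id = ids[idx], event_date = dt, setting = setting,
        dx_codes = dx, dx_system = ifelse(icd10, "ICD10", "ICD9"),
        stringsAsFactors = FALSE
      )
    }
    hospital$case <- mk_hosp(hosp_i, "INPATIENT")
    hospital$case_er <- mk_hosp(er_i, "ER")

    ## drug claims for senior cases (pharmacy observed from age 65)
    sci <- ci[is_senior[ci]]
    if (length(sci)) {
      drows <- list()
      for (cls in names(p$drug_probs_case)) {
        take <- sci[stats::runif(length(sci)) < p$drug_probs_case[[cls]]]
        if (!length(take)) next
        nfill <- 1L + stats::rpois(length(take), 3)
        pid <- rep(ids[take], nfill)
        o <- onset[match(take, ci)]
        e <- act_end[match(take, ci)]
        drows[[cls]] <- data.frame(
          patient_id = pid,
          dispense_date = runif_days(sum(nfill), rep(o, nfill), rep(e, nfill)),
          drug_class = cls, stringsAsFactors = FALSE
        )
      }
      drugs$case <- do.call(rbind, drows)
    }
  }

  ## ---- possible-RA streams: weakly coded, never specialist-confirmed
  pi_ <- which(is_possible)
  if (length(pi_)) {
    coded <- stats::runif(length(pi_)) < 0.5
    take <- pi_[coded]
    if (length(take)) {
      ncl <- 1L + stats::rbinom(length(take), 1L, 0.3)
      pid <- rep(ids[take], ncl)
      claims$possible <- data.frame(
        patient_id = pid,
        service_date = runif_days(length(pid), p$obs_start, p$obs_end),
        dx_code = "714", dx_system = "OHIP_DX", specialty = "family medicine",
        stringsAsFactors = FALSE
      )
    }
  }

  ## ---- non-case RA miscoding (clustered in a one-year episode)
  ni <- which(!is_case)
  mis <- ni[stats::runif(length(ni)) < p$p_noncase_ever_coded]
  if (length(mis)) {
    nmc <- 1L + stats::rpois(length(mis), 0.35)
    centre <- runif_days(length(mis), p$obs_start, p$obs_end - 365L)
    pid <- rep(ids[mis], nmc)
    start <- rep(centre, nmc)
    dts <- start + floor(stats::runif(sum(nmc)) * 365)
    msk <- stats::runif(sum(nmc)) < p$p_msk_miscode
    claims$miscode <- data.frame(
      patient_id = pid, service_date = pmin(dts, p$obs_end),
      dx_code = "714", dx_system = "OHIP_DX",
      specialty = ifelse(
        msk,
        sample(c("internal medicine", "orthopedic surgery"), sum(nmc),
               replace = TRUE, prob = c(0.7, 0.3)),
        "family medicine"
      ),
      stringsAsFactors = FALSE
    )
  }
  mk_nc_hosp <- function(prob, setting) {
    take <- ni[stats::runif(length(ni)) < prob]
    if (!length(take)) return(NULL)
    dt <- runif_days(length(take), p$obs_start, p$obs_end)
    icd10 <- dt >= as.Date("2002-01-01")
    data.frame(
      patient_id = ids[take], event_date = dt, setting = setting,
      dx_codes = ifelse(icd10, "M06.9", "714"),
      dx_system = ifelse(icd10, "ICD10", "ICD9"), stringsAsFactors = FALSE
    )
  }
  hospital$nc <- mk_nc_hosp(p$p_noncase_hosp_ra, "INPATIENT")
  hospital$nc_er <- mk_nc_hosp(p$p_noncase_er_ra, "ER")

  ## ---- non-case senior drug exposure
  sni <- ni[is_senior[ni]]
  if (length(sni)) {
    drows <- list()
    for (cls in names(p$drug_probs_noncase)) {
      take <- sni[stats::runif(length(sni)) < p$drug_probs_noncase[[cls]]]
      if (!length(take)) next
      nfill <- 1L + stats::rpois(length(take), 2)
      drows[[cls]] <- data.frame(
        patient_id = rep(ids[take], nfill),
        dispense_date = runif_days(sum(nfill), p$obs_start, p$obs_end),
        drug_class = cls, stringsAsFactors = FALSE
      )
    }
    drugs$nc <- do.call(rbind, drows)
  }

  bind <- function(lst) {
    lst <- lst[!vapply(lst, is.null, TRUE)]
    if (!length(lst)) return(NULL)
    do.call(rbind, lst)
  }
  ra_cohort(
    patients = data.frame(patient_id = ids, birth_date = birth, sex = sex,
                          stringsAsFactors = FALSE),
    claims = bind(claims), hospital = bind(hospital), drugs = bind(drugs),
    labels = data.frame(patient_id = ids, status = status, stringsAsFactors = FALSE),
    obs_start = p$obs_start, obs_end = p$obs_end, index_date = p$index_date
  )
}

#' Realized marginal rates of a generated cohort
#'
#' Computes, exactly from the event streams, the quantities the generator
#' plants: prevalence by stratum, the fraction of cases/non-cases ever
#' RA-coded in billing, RA hospitalization rates, specialist involvement
#' among coded cases, and drug exposure among senior cases. Used by the
#' parameter-recovery tests and for auditing a simulated cohort.
#'
#' @param cohort A labelled `ra_cohort` (e.g. from [generate_cohort()]).
#' @param config An `ra_code_config`.
#' @return Named list of realized proportions and counts.
#' @export
planted_truth_report <- function(cohort, config = default_code_config()) {
  stopifnot(inherits(cohort, "ra_cohort"))
  if (!nrow(cohort$patients)) stop("empty cohort")
  if (!nrow(cohort$labels)) stop("cohort has no reference labels")
  case <- apply_reference_definition(cohort$labels, "DEFINITE_ONLY")
  ids <- cohort$patients$patient_id
  case <- case[ids]
  age <- age_at(cohort$patients$birth_date, cohort$index_date)
  senior <- age >= 65L

  ra_claim <- if (nrow(cohort$claims)) {
    classify_code(cohort$claims$dx_code, cohort$claims$dx_system, config) == "RA"
  } else {
    logical()
  }
  coded_ids <- unique(cohort$claims$patient_id[ra_claim])
  ever_coded <- ids %in% coded_ids
  spec_ids <- unique(cohort$claims$patient_id[
    ra_claim & is_msk_specialist(cohort$claims$specialty, config)
  ])

  hosp_ra_ids <- character()
  if (nrow(cohort$hospital)) {
    hs <- cohort$hospital[cohort$hospital$setting == "INPATIENT", , drop = FALSE]
    if (nrow(hs)) {
      lists <- strsplit(hs$dx_codes, ";", fixed = TRUE)
      lens <- lengths(lists)
      cls <- classify_code(unlist(lists), rep(hs$dx_system, lens), config)
      grp <- factor(rep(seq_along(lists), lens), levels = seq_along(lists))
      hosp_ra_ids <- unique(hs$patient_id[rowsum(as.integer(cls == "RA"), grp)[, 1] > 0L])
    }
  }

  senior_case_ids <- ids[case & senior]
  drug_rate <- function(cls) {
    if (!length(senior_case_ids)) return(NA_real_)
    exposed <- unique(cohort$drugs$patient_id[cohort$drugs$drug_class == cls])
    mean(senior_case_ids %in% exposed)
  }

  list(
    n = length(ids),
    n_cases = sum(case),
    prevalence = mean(case),
    prevalence_adult = mean(case[age >= 20L & !senior]),
    prevalence_senior = if (any(senior)) mean(case[senior]) else NA_real_,
    p_case_ever_coded = if (any(case)) mean(ever_coded[case]) else NA_real_,
    p_noncase_ever_coded = if (any(!case)) mean(ever_coded[!case]) else NA_real_,
    p_case_specialist = if (any(case & ever_coded)) {
      mean(ids[case & ever_coded] %in% spec_ids)
    } else NA_real_,
    p_case_hosp = if (any(case)) mean(ids[case] %in% hosp_ra_ids) else NA_real_,
    drug_rates_senior_cases = c(
      DMARD = drug_rate("DMARD"),
      GLUCOCORTICOSTEROID = drug_rate("GLUCOCORTICOSTEROID"),
      BIOLOGIC = drug_rate("BIOLOGIC"),
      NSAID_COXIB = drug_rate("NSAID_COXIB")
    )
  )
}
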