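# Case-ascertainment rule engine.
#
# An algorithm is an OR of clauses. Each clause counts RA-coded encounters
# from one source (physician billing, inpatient, ER) inside a temporal
# window, optionally with a minimum gap between counted encounters, a
# musculoskeletal-specialist requirement (>=1 of the counted encounters), and
# a drug-claim co-requirement (seniors only, since pharmacy claims begin at
# age 65). Optional exclusion rules then demote positives: Case A (an
# other-rheumatology code after the last RA billing code) and Case B (a
# rheumatologist visit without an RA code on/after the first RA billing
# code).

CLAUSE_SOURCES <- c("P" = "PHYSICIAN", "H" = "HOSPITAL", "ER" = "ER")
DEFAULT_RX_CLASSES <- c("DMARD", "BIOLOGIC", "GLUCOCORTICOSTEROID")

#' Construct a clause of a case-ascertainment algorithm
#'
#' @param source `"PHYSICIAN"`, `"HOSPITAL"`, or `"ER"` (or the short forms
#'   `"P"`, `"H"`, `"ER"`).
#' @param n_codes Number of distinct RA-coded encounter dates required
#'   (same-day claims collapse to one date unless the evaluator is run with
#'   `count_same_day = TRUE`).
#' @param window_days All counted encounters must fit in one interval of this
#'   length, endpoints inclusive (`Inf` = "ever"). Conventions: 1 year = 365
#'   days, 8 weeks = 56 days.
#' @param min_gap_days Minimum days between consecutive counted encounters.
#' @param require_specialist At least one counted encounter must carry an MSK
#'   specialty.
#' @param require_rx Additionally require >=1 drug claim in `rx_classes`;
#'   under a finite window the drug claim must fit in the same
#'   `window_days`-long interval as the counted encounters, under "ever" it
#'   may fall anywhere in the observation window. Evaluates to `FALSE` for
#'   patients younger than 65 at the index date.
#' @param rx_classes Drug classes satisfying `require_rx`.
#' @return An object of class `ra_clause`.
#' @export
ra_clause <- function(source, n_codes, window_days = Inf, min_gap_days = 0L,
                      require_specialist = FALSE, require_rx = FALSE,
                      rx_classes = DEFAULT_RX_CLASSES) {
  source <- as.character(source)
  if (source %in% names(CLAUSE_SOURCES)) source <- CLAUSE_SOURCES[[source]]
  if (!source %in% CLAUSE_SOURCES) {
    stop("unknown clause source: ", source,
         " (expected PHYSICIAN, HOSPITAL or ER)")
  }
  n_codes <- as.integer(n_codes)
  if (is.na(n_codes) || n_codes < 1L) stop("n_codes must be a positive integer")
  if (!is.infinite(window_days)) {
    window_days <- as.integer(window_days)
    if (is.na(window_days) || window_days < 1L) stop("window_days must be positive or Inf")
  }
  min_gap_days <- as.integer(min_gap_days)
  if (is.na(min_gap_days) || min_gap_days < 0L) stop("min_gap_days must be >= 0")
  if (is.finite(window_days) && window_days < min_gap_days * (n_codes - 1L)) {
    warning("clause is unsatisfiable: window_days < min_gap_days * (n_codes - 1)")
  }
  bad <- setdiff(rx_classes, DRUG_CLASSES)
  if (length(bad)) stop("unknown rx class(es): ", paste(bad, collapse = ", "))
  structure(
    list(
      source = source, n_codes = n_codes, window_days = window_days,
      min_gap_days = min_gap_days,
      require_specialist = isTRUE(require_specialist),
      require_rx = isTRUE(require_rx),
      rx_classes = rx_classes
    ),
    class = "ra_clause"
  )
}

#' Construct a case-ascertainment algorithm
#'
#' Clauses are combined by OR; a patient is classified positive when any
#' clause is satisfied and no enabled exclusion triggers.
#'
#' @param algorithm_id Identifier used in reports.
#' @param clauses A single `ra_clause` or a list of them (non-empty).
#' @param exclude_a,exclude_b Enable exclusion Case A / Case B.
#' @param age_subset Optional minimum age (e.g. `65` for drug-requiring
#'   definitions, which only apply to seniors).
#' @return An object of class `ra_algorithm`.
#' @examples
#' # "(1 H ever) OR (3 P with >=1 P by a specialist in 2 YR)"
#' alg <- ra_algorithm("opt", list(
#'   ra_clause("HOSPITAL", 1),
#'   ra_clause("PHYSICIAN", 3, window_days = 730, require_specialist = TRUE)
#' ))
#' render_algorithm(alg)
#' @export
ra_algorithm <- function(algorithm_id, clauses, exclude_a = FALSE,
                         exclude_b = FALSE, age_subset = NULL) {
  if (inherits(clauses, "ra_clause")) clauses <- list(clauses)
  if (!length(clauses) || !all(vapply(clauses, inherits, TRUE, "ra_clause"))) {
    stop("clauses must be a non-empty list of ra_clause objects")
  }
  if (!is.null(age_subset)) age_subset <- as.integer(age_subset)
  structure(
    list(
      algorithm_id = as.character(algorithm_id), clauses = clauses,
      exclude_a = isTRUE(exclude_a), exclude_b = isTRUE(exclude_b),
      age_subset = age_subset
    ),
    class = "ra_algorithm"
  )
}

#' @export
print.ra_algorithm <- function(x, ...) {
  cat("<ra_algorithm> ", x$algorithm_id, ": ", render_algorithm(x), "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# mini-DSL mirroring the published row labels, e.g.
#   "1H | 3P(spec>=1)/2y"          (1 H ever) OR (3 P, >=1 specialist, 2 years)
#   "1H | 2P(gap>=56d)/2y excl(A,B)"
#   "2P(rx>=1)/1y"                 2 P plus >=1 RA drug claim in 1 year

#' Parse the algorithm mini-grammar
#'
#' Grammar: clauses joined by `|`; each clause is
#' `<n><source>[(opts)][/<window>]` with source `P`, `H` or `ER`, options
#' among `spec>=1`, `gap>=<days>d`, `rx>=1` (comma-separated), and window
#' `<k>y` (k*365 days) or `<k>d`; a missing window means "ever". An optional
#' trailing `excl(A)`, `excl(B)` or `excl(A,B)` enables the exclusion rules.
#'
#' `parse_algorithm()` and [render_algorithm()] round-trip: rendering is
#' canonical and re-parses to the identical algorithm.
#'
#' @param text Algorithm text, e.g. `"1H | 3P(spec>=1)/2y"`.
#' @param algorithm_id Identifier; defaults to the canonical rendering.
#' @param age_subset Optional minimum age, see [ra_algorithm()].
#' @return An `ra_algorithm`.
#' @examples
#' parse_algorithm("1H | 2P(gap>=56d)/2y excl(A,B)")
#' @export
parse_algorithm <- function(text, algorithm_id = NULL, age_subset = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  rest <- trimws(text)
  exclude_a <- FALSE
  exclude_b <- FALSE
  m <- regexec("\\s*excl\\(([^()]*)\\)\\s*$", rest)[[1]]
  if (m[1] != -1L) {
    flags <- trimws(strsplit(regmatches(rest, list(m))[[1]][2], ",")[[1]])
    bad <- setdiff(flags, c("A", "B"))
    if (length(bad)) {
      stop("syntax error in '", text, "': unknown exclusion flag(s) ",
           paste(bad, collapse = ", "), " at position ", m[1])
    }
    exclude_a <- "A" %in% flags
    exclude_b <- "B" %in% flags
    rest <- substr(rest, 1L, m[1] - 1L)
  }
  parts <- trimws(strsplit(rest, "|", fixed = TRUE)[[1]])
  if (!length(parts) || any(!nzchar(parts)) || grepl("\\|\\s*$", rest)) {
    stop("syntax error in '", text, "': empty clause")
  }
  clauses <- lapply(parts, parse_clause, full = text)
  alg <- ra_algorithm(algorithm_id %||% "", clauses,
                      exclude_a = exclude_a, exclude_b = exclude_b,
                      age_subset = age_subset)
  if (!nzchar(alg$algorithm_id)) alg$algorithm_id <- render_algorithm(alg)
  alg
}

parse_clause <- function(part, full) {
  pat <- "^([0-9]+)\\s*(ER|P|H)\\s*(\\(([^()]*)\\))?\\s*(/\\s*([0-9]+)\\s*([yd]))?$"
  m <- regexec(pat, part)[[1]]
  if (m[1] == -1L) {
    stop("syntax error in '", full, "': cannot parse clause '", part, "'")
  }
  g <- regmatches(part, list(regexec(pat, part)[[1]]))[[1]]
  n <- as.integer(g[2])
  if (n < 1L) stop("syntax error in '", full, "': n must be >= 1 in '", part, "'")
  source <- CLAUSE_SOURCES[[g[3]]]
  window <- Inf
  if (nzchar(g[7])) {
    k <- as.integer(g[7])
    window <- if (g[8] == "y") k * 365L else k
    if (window < 1L) stop("syntax error in '", full, "': non-positive window in '", part, "'")
  }
  gap <- 0L
  spec <- FALSE
  rx <- FALSE
  if (nzchar(g[5])) {
    for (opt in trimws(strsplit(g[5], ",")[[1]])) {
      if (opt == "spec>=1") {
        spec <- TRUE
      } else if (opt == "rx>=1") {
        rx <- TRUE
      } else if (grepl("^gap>=[0-9]+d$", opt)) {
        gap <- as.integer(sub("^gap>=([0-9]+)d$", "\\1", opt))
      } else {
        stop("syntax error in '", full, "': unknown option '", opt, "' in '", part, "'")
      }
    }
  }
  ra_clause(source, n, window_days = window, min_gap_days = gap,
            require_specialist = spec, require_rx = rx)
}

#' Render an algorithm to its canonical grammar string
#' @param alg An `ra_algorithm` (or `ra_clause`).
#' @return A single string in the grammar of [parse_algorithm()].
#' @export
render_algorithm <- function(alg) {
  if (inherits(alg, "ra_clause")) return(render_clause(alg))
  stopifnot(inherits(alg, "ra_algorithm"))
  txt <- paste(vapply(alg$clauses, render_clause, character(1)), collapse = " | ")
  flags <- c(if (alg$exclude_a) "A", if (alg$exclude_b) "B")
  if (length(flags)) txt <- paste0(txt, " excl(", paste(flags, collapse = ","), ")")
  txt
}

render_clause <- function(cl) {
  src <- names(CLAUSE_SOURCES)[match(cl$source, CLAUSE_SOURCES)]
  opts <- c(
    if (cl$min_gap_days > 0L) paste0("gap>=", cl$min_gap_days, "d"),
    if (cl$require_specialist) "spec>=1",
    if (cl$require_rx) "rx>=1"
  )
  win <- if (is.finite(cl$window_days)) {
    if (cl$window_days %% 365L == 0L) {
      paste0("/", cl$window_days %/% 365L, "y")
    } else {
      paste0("/", cl$window_days, "d")
    }
  }
  paste0(cl$n_codes, src,
         if (length(opts)) paste0("(", paste(opts, collapse = ","), ")"),
         win %||% "")
}

#' Read an algorithm set from JSON
#'
#' The file is an array of objects `{algorithm_id, dsl, age_subset}` with
#' `age_subset` null or a minimum age. The packaged set (the default) encodes
#' the 43 published validation-study case definitions: 28 for the full adult
#' cohort and 15 drug-requiring ones restricted to seniors.
#'
#' @param path JSON file; defaults to the packaged `algorithms.json`.
#' @return Named list of `ra_algorithm` objects.
#' @export
read_algorithms <- function(path = system.file("extdata", "algorithms.json",
                                               package = "raclaims")) {
  if (!file.exists(path)) stop("algorithms file not found: ", path)
  spec <- jsonlite::read_json(path)
  algs <- lapply(spec, function(s) {
    parse_algorithm(s$dsl, algorithm_id = s$algorithm_id,
                    age_subset = s$age_subset)
  })
  stats::setNames(algs, vapply(algs, `[[`, character(1), "algorithm_id"))
}

#' @rdname read_algorithms
#' @export
default_algorithms <- function() read_algorithms()

# ---------------------------------------------------------------------------
# per-patient building blocks

#' Qualifying physician claim dates
#'
#' Distinct service dates carrying at least one RA-classified physician
#' billing claim, each flagged for whether any RA claim that day was billed
#' by an MSK specialist. Same-day duplicate claims collapse to one date
#' (billing commonly emits several claims per encounter) unless
#' `count_same_day = TRUE`.
#'
#' @param patient An `ra_patient` (see [patient_record()]).
#' @param config An `ra_code_config`.
#' @param count_same_day Count same-day RA claims separately (sensitivity
#'   analyses only).
#' @return Data frame with columns `date` (Date, ascending) and `specialist`
#'   (logical).
#' @export
qualifying_physician_dates <- function(patient, config = default_code_config(),
                                       count_same_day = FALSE) {
  cl <- patient$claims
  if (!nrow(cl)) {
    return(data.frame(date = as.Date(character()), specialist = logical()))
  }
  is_ra <- classify_code(cl$dx_code, cl$dx_system, config) == "RA"
  cl <- cl[is_ra, , drop = FALSE]
  if (!nrow(cl)) {
    return(data.frame(date = as.Date(character()), specialist = logical()))
  }
  msk <- is_msk_specialist(cl$specialty, config)
  if (count_same_day) {
    ord <- order(cl$service_date)
    return(data.frame(date = cl$service_date[ord], specialist = msk[ord]))
  }
  agg <- rowsum(as.integer(msk), group = as.integer(cl$service_date))
  days <- as.integer(rownames(agg))
  ord <- order(days)
  data.frame(
    date = as.Date(days[ord], origin = "1970-01-01"),
    specialist = agg[ord, 1] > 0L
  )
}

hospital_ra_days <- function(hospital, setting, config) {
  hs <- hospital[hospital$setting == setting, , drop = FALSE]
  if (!nrow(hs)) return(integer())
  lists <- strsplit(hs$dx_codes, ";", fixed = TRUE)
  lens <- lengths(lists)
  cls <- classify_code(unlist(lists), rep(hs$dx_system, lens), config)
  grp <- factor(rep(seq_along(lists), lens), levels = seq_along(lists))
  has_ra <- rowsum(as.integer(cls == "RA"), grp)[, 1] > 0L
  sort(unique(as.integer(hs$event_date[has_ra])))
}

#' Any RA-coded hospital record, ever?
#'
#' RA counts in any diagnosis position (primary or secondary) of an
#' inpatient or ER record, across both the ICD-9 (pre-2002) and ICD-10 eras.
#'
#' @inheritParams qualifying_physician_dates
#' @param setting `"INPATIENT"` or `"ER"`.
#' @return Logical scalar.
#' @export
hospital_ra_ever <- function(patient, setting = c("INPATIENT", "ER"),
                             config = default_code_config()) {
  setting <- match.arg(setting)
  length(hospital_ra_days(patient$hospital, setting, config)) > 0L
}

# ---------------------------------------------------------------------------
# exact windowed chain search
#
# chain_earliest() finds the earliest date D such that n of the given
# (ascending, distinct, integer) dates fit in a window of window_days ending
# no later than D, with consecutive chosen dates >= gap apart, >=1 chosen
# date flagged specialist if required, and D the latest chosen date. It
# scans candidate last dates in ascending order; for each, a longest
# minimum-gap-chain dynamic program decides whether a qualifying subset
# ending there exists. Fast paths cover the common gap-free clauses.

chain_earliest <- function(d, sp, n, window_days = Inf, gap = 0L,
                           req_spec = FALSE) {
  m <- length(d)
  if (n < 1L) stop("n must be >= 1")
  if (m < n) return(NA_integer_)

  if (gap == 0L && !req_spec) {
    idx <- n:m
    ok <- if (is.finite(window_days)) d[idx] - d[idx - n + 1L] <= window_days else rep(TRUE, length(idx))
    hit <- which(ok)
    return(if (length(hit)) d[idx[hit[1L]]] else NA_integer_)
  }

  if (gap == 0L && req_spec) {
    for (j in seq.int(n, m)) {
      lo <- if (is.finite(window_days)) d[j] - window_days else -Inf
      in_win <- which(d >= lo & seq_len(m) <= j)
      if (length(in_win) < n) next
      if (sp[j] || (n >= 2L && any(sp[in_win]))) return(d[j])
    }
    return(NA_integer_)
  }

  # general case: minimum-gap chains
  for (j in seq.int(n, m)) {
    lo <- if (is.finite(window_days)) d[j] - window_days else -Inf
    keep <- which(d >= lo & seq_len(m) <= j)
    dd <- d[keep]
    ss <- sp[keep]
    k <- length(dd)
    if (k < n) next
    # B[i]: longest chain (gaps >= gap) within the window ending at i
    B <- integer(k)
    for (i in seq_len(k)) {
      prev <- if (i > 1L) which(dd[seq_len(i - 1L)] <= dd[i] - gap) else integer()
      B[i] <- 1L + (if (length(prev)) max(B[prev]) else 0L)
    }
    if (!req_spec) {
      if (B[k] >= n) return(d[j])
      next
    }
    # G[i]: longest chain starting at i and ending at the last in-window
    # date (index k); NA when k is unreachable from i under the gap
    G <- rep(NA_integer_, k)
    G[k] <- 1L
    if (k > 1L) {
      for (i in rev(seq_len(k - 1L))) {
        nxt <- which(seq_len(k) > i & dd >= dd[i] + gap & !is.na(G))
        if (length(nxt)) G[i] <- 1L + max(G[nxt])
      }
    }
    # a specialist date s can sit inside a qualifying subset ending at k iff
    # chains through s reach total length n; trimming to exactly n keeps s
    # and the last date, which needs n >= 2 unless s is the last date
    ok <- any(ss & !is.na(G) & (B + G - 1L >= n) & (seq_len(k) == k | n >= 2L))
    if (ok) return(d[j])
  }
  NA_integer_
}

#' Earliest window qualification date
#'
#' Given ascending, de-duplicated qualifying dates, returns the earliest date
#' `D` such that some `n` of them, ending at `D`, span at most `window_days`
#' (endpoints inclusive), have consecutive members at least `min_gap_days`
#' apart, and include at least one specialist-flagged date when
#' `require_specialist`. Returns `NA` when no such subset exists.
#'
#' @param dates Ascending Date vector without duplicates.
#' @param n Required number of dates (>= 1).
#' @param window_days Window length in days, or `Inf` for "ever".
#' @param min_gap_days Minimum gap between consecutive counted dates.
#' @param require_specialist Require a specialist-flagged date in the subset.
#' @param specialist Logical vector parallel to `dates`.
#' @return A Date, or `NA` (`as.Date(NA)`) when unsatisfied.
#' @examples
#' d <- as.Date("2000-01-01") + c(0, 300, 400)
#' window_satisfied(d, n = 3, window_days = 730) # qualifies at day 400
#' @export
window_satisfied <- function(dates, n, window_days = Inf, min_gap_days = 0L,
                             require_specialist = FALSE,
                             specialist = rep(FALSE, length(dates))) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  if (is.finite(window_days) && window_days < min_gap_days * (n - 1L)) {
    warning("unsatisfiable: window_days < min_gap_days * (n - 1)")
  }
  d <- as.integer(as.Date(dates))
  if (is.unsorted(d, strictly = TRUE)) {
    stop("dates must be strictly ascending and de-duplicated")
  }
  res <- chain_earliest(d, as.logical(specialist), n,
                        window_days = window_days,
                        gap = as.integer(min_gap_days),
                        req_spec = isTRUE(require_specialist))
  if (is.na(res)) as.Date(NA) else as.Date(res, origin = "1970-01-01")
}

# evaluate one clause against precomputed per-patient streams; returns the
# qualification date (integer day) or NA
eval_clause_pre <- function(clause, pre) {
  src <- clause$source
  if (src == "PHYSICIAN") {
    d <- pre$phys_days
    sp <- pre$phys_spec
  } else if (src == "HOSPITAL") {
    d <- pre$hosp_days
    sp <- rep(FALSE, length(d))
  } else {
    d <- pre$er_days
    sp <- rep(FALSE, length(d))
  }
  if (!clause$require_rx) {
    return(chain_earliest(d, sp, clause$n_codes, clause$window_days,
                          clause$min_gap_days, clause$require_specialist))
  }
  # drug-requiring clause: pharmacy coverage starts at 65
  if (is.na(pre$age) || pre$age < 65L) return(NA_integer_)
  rx <- pre$drug_days[pre$drug_class %in% clause$rx_classes]
  if (!length(rx)) return(NA_integer_)
  rx <- sort(unique(rx))
  if (!is.finite(clause$window_days)) {
    return(chain_earliest(d, sp, clause$n_codes, Inf,
                          clause$min_gap_days, clause$require_specialist))
  }
  # all required events (n encounters + >=1 drug claim) must fit in one
  # interval of length window_days; any satisfying interval can slide right
  # until its left edge hits an event, so event days enumerate the candidates
  best <- NA_integer_
  for (L in sort(unique(c(d, rx)))) {
    hi <- L + clause$window_days
    if (!any(rx >= L & rx <= hi)) next
    inside <- d >= L & d <= hi
    if (sum(inside) < clause$n_codes) next
    q <- chain_earliest(d[inside], sp[inside], clause$n_codes, Inf,
                        clause$min_gap_days, clause$require_specialist)
    if (!is.na(q) && (is.na(best) || q < best)) best <- q
  }
  best
}

precompute_patient <- function(patient, config, count_same_day = FALSE) {
  qp <- qualifying_physician_dates(patient, config, count_same_day)
  list(
    phys_days = as.integer(qp$date),
    phys_spec = qp$specialist,
    hosp_days = hospital_ra_days(patient$hospital, "INPATIENT", config),
    er_days = hospital_ra_days(patient$hospital, "ER", config),
    drug_days = as.integer(patient$drugs$dispense_date),
    drug_class = patient$drugs$drug_class,
    age = age_at(patient$birth_date, patient$index_date)
  )
}

#' Drug co-requirement of a clause
#'
#' Evaluates the combined encounter-plus-drug requirement of a
#' `require_rx` clause for one patient: `TRUE` iff the patient is 65+ at the
#' index date, has the required encounters, and a drug claim of an accepted
#' class falls in the same `window_days` interval (anywhere in the
#' observation window when the clause window is `Inf`).
#'
#' @inheritParams qualifying_physician_dates
#' @param clause An `ra_clause` with `require_rx = TRUE`.
#' @return Logical scalar.
#' @export
rx_satisfied <- function(patient, clause, config = default_code_config()) {
  stopifnot(inherits(clause, "ra_clause"))
  if (!clause$require_rx) {
    stop("rx_satisfied() expects a clause with require_rx = TRUE")
  }
  pre <- precompute_patient(patient, config)
  !is.na(eval_clause_pre(clause, pre))
}

exclusion_flags <- function(claims, config) {
  # physician billing claims only; hospital codes never trigger exclusions
  if (!nrow(claims)) return(c(a = FALSE, b = FALSE))
  cls <- classify_code(claims$dx_code, claims$dx_system, config)
  ra_days <- as.integer(claims$service_date[cls == "RA"])
  if (!length(ra_days)) return(c(a = FALSE, b = FALSE)) # nothing to anchor on
  other_days <- as.integer(claims$service_date[cls == "OTHER_RHEUM"])
  a <- length(other_days) > 0L && any(other_days > max(ra_days))
  rheum <- normalize_specialty(claims$specialty) == "rheumatology"
  b <- any(rheum & cls != "RA" & as.integer(claims$service_date) >= min(ra_days))
  c(a = a, b = b)
}

#' Does an exclusion rule trigger for a patient?
#'
#' Case A: any physician claim with an other-rheumatology code strictly after
#' the patient's last RA-coded physician claim. Case B: any physician claim
#' billed under the rheumatology specialty, dated on or after the first
#' RA-coded claim, that carries a non-RA diagnosis. Both scan physician
#' billing only; a patient with no RA-coded physician claims (e.g. a
#' hospital-only positive) triggers neither. These anchors (last RA claim for
#' A, first RA claim for B) are this package's operational reading of the
#' published one-sentence rule and are documented as such.
#'
#' @inheritParams qualifying_physician_dates
#' @param exclude_a,exclude_b Which cases are enabled.
#' @return Logical scalar: `TRUE` if any enabled case triggers.
#' @export
exclusion_triggered <- function(patient, exclude_a = TRUE, exclude_b = TRUE,
                                config = default_code_config()) {
  fl <- exclusion_flags(patient$claims, config)
  (isTRUE(exclude_a) && fl[["a"]]) || (isTRUE(exclude_b) && fl[["b"]])
}

#' Evaluate an algorithm for one patient
#'
#' Deterministic and independent of event input order: positive iff any
#' clause is satisfied and no enabled exclusion triggers.
#'
#' @inheritParams qualifying_physician_dates
#' @param alg An `ra_algorithm`.
#' @return Logical scalar.
#' @examples
#' p <- patient_record("x", "1950-06-01", claims = data.frame(
#'   service_date = c("2003-01-10", "2003-03-01", "2003-06-15"),
#'   dx_code = "714", dx_system = "OHIP_DX", specialty = "rheumatology"
#' ))
#' evaluate_algorithm(parse_algorithm("3P(spec>=1)/1y"), p)
#' @export
evaluate_algorithm <- function(alg, patient, config = default_code_config(),
                               count_same_day = FALSE) {
  stopifnot(inherits(alg, "ra_algorithm"), inherits(patient, "ra_patient"))
  pre <- precompute_patient(patient, config, count_same_day)
  if (!is.null(alg$age_subset) && (is.na(pre$age) || pre$age < alg$age_subset)) {
    return(FALSE)
  }
  positive <- FALSE
  for (cl in alg$clauses) {
    if (!is.na(eval_clause_pre(cl, pre))) {
      positive <- TRUE
      break
    }
  }
  if (!positive) return(FALSE)
  if (alg$exclude_a || alg$exclude_b) {
    if (exclusion_triggered(patient, alg$exclude_a, alg$exclude_b, config)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Evaluate algorithms across a cohort
#'
#' Classifies every patient in the chosen age subset under every algorithm.
#' Only patients with at least one RA-coded event anywhere in their streams
#' can be positive, so the per-patient engine runs on that candidate set and
#' everyone else is negative; results are identical to calling
#' [evaluate_algorithm()] per patient.
#'
#' @param cohort An `ra_cohort`.
#' @param algorithms A named list of `ra_algorithm`s (e.g.
#'   [default_algorithms()]), or a single `ra_algorithm`.
#' @param config An `ra_code_config`.
#' @param subset `"all"`, `"adults"` (age >= 20 at the index date) or
#'   `"seniors"` (>= 65).
#' @param count_same_day See [qualifying_physician_dates()].
#' @return Logical matrix, rows = patient ids in the subset, columns =
#'   algorithm ids.
#' @export
evaluate_cohort <- function(cohort, algorithms,
                            config = default_code_config(),
                            subset = c("all", "adults", "seniors"),
                            count_same_day = FALSE) {
  stopifnot(inherits(cohort, "ra_cohort"))
  subset <- match.arg(subset)
  if (inherits(algorithms, "ra_algorithm")) {
    algorithms <- stats::setNames(list(algorithms), algorithms$algorithm_id)
  }
  stopifnot(length(algorithms) >= 0, all(vapply(algorithms, inherits, TRUE, "ra_algorithm")))

  ages <- age_at(cohort$patients$birth_date, cohort$index_date)
  cutoff <- switch(subset, all = 0L, adults = 20L, seniors = 65L)
  pids <- cohort$patients$patient_id[ages >= cutoff]
  age_by_pid <- stats::setNames(ages[ages >= cutoff], pids)

  alg_ids <- vapply(algorithms, `[[`, character(1), "algorithm_id")
  out <- matrix(FALSE, nrow = length(pids), ncol = length(algorithms),
                dimnames = list(pids, alg_ids))
  if (!length(algorithms) || !length(pids)) return(out)

  keep <- function(df, datecol) df[df$patient_id %in% pids, , drop = FALSE]
  claims <- keep(cohort$claims)
  hospital <- keep(cohort$hospital)
  drugs <- keep(cohort$drugs)

  # qualifying physician dates for all patients at once
  qp <- data.frame(pid = character(), day = integer(), spec = logical())
  if (nrow(claims)) {
    is_ra <- classify_code(claims$dx_code, claims$dx_system, config) == "RA"
    rac <- claims[is_ra, , drop = FALSE]
    if (nrow(rac)) {
      dt <- data.table::data.table(
        pid = rac$patient_id, day = as.integer(rac$service_date),
        msk = is_msk_specialist(rac$specialty, config)
      )
      if (count_same_day) {
        qp <- dt[order(pid, day), .(pid, day, spec = msk)]
      } else {
        qp <- dt[, .(spec = any(msk)), by = .(pid, day)][order(pid, day)]
      }
      qp <- as.data.frame(qp)
    }
  }

  hosp_by <- list(INPATIENT = list(), ER = list())
  if (nrow(hospital)) {
    for (setting in SETTINGS) {
      hs <- hospital[hospital$setting == setting, , drop = FALSE]
      if (!nrow(hs)) next
      lists <- strsplit(hs$dx_codes, ";", fixed = TRUE)
      lens <- lengths(lists)
      cls <- classify_code(unlist(lists), rep(hs$dx_system, lens), config)
      grp <- factor(rep(seq_along(lists), lens), levels = seq_along(lists))
      has_ra <- rowsum(as.integer(cls == "RA"), grp)[, 1] > 0L
      ra_rec <- hs[has_ra, , drop = FALSE]
      hosp_by[[setting]] <- lapply(
        split(as.integer(ra_rec$event_date), ra_rec$patient_id),
        function(x) sort(unique(x))
      )
    }
  }

  drugs_by <- if (nrow(drugs)) split(drugs, drugs$patient_id) else list()

  needs_excl <- any(vapply(algorithms, function(a) a$exclude_a || a$exclude_b, TRUE))
  claims_by <- if ((needs_excl) && nrow(claims)) split(claims, claims$patient_id) else list()

  qp_by <- if (nrow(qp)) split(qp[c("day", "spec")], qp$pid) else list()

  candidates <- unique(c(names(qp_by), names(hosp_by$INPATIENT), names(hosp_by$ER)))
  empty_drug <- list(drug_days = integer(), drug_class = character())

  for (pid in candidates) {
    q <- qp_by[[pid]]
    dg <- drugs_by[[pid]]
    pre <- list(
      phys_days = if (is.null(q)) integer() else q$day,
      phys_spec = if (is.null(q)) logical() else q$spec,
      hosp_days = hosp_by$INPATIENT[[pid]] %||% integer(),
      er_days = hosp_by$ER[[pid]] %||% integer(),
      drug_days = if (is.null(dg)) integer() else as.integer(dg$dispense_date),
      drug_class = if (is.null(dg)) character() else dg$drug_class,
      age = age_by_pid[[pid]]
    )
    excl <- NULL
    clause_cache <- new.env(parent = emptyenv())
    for (ai in seq_along(algorithms)) {
      alg <- algorithms[[ai]]
      if (!is.null(alg$age_subset) && pre$age < alg$age_subset) next
      positive <- FALSE
      for (cl in alg$clauses) {
        key <- render_clause(cl)
        hit <- clause_cache[[key]]
        if (is.null(hit)) {
          hit <- !is.na(eval_clause_pre(cl, pre))
          clause_cache[[key]] <- hit
        }
        if (hit) {
          positive <- TRUE
          break
        }
      }
      if (positive && (alg$exclude_a || alg$exclude_b)) {
        if (is.null(excl)) {
          pc <- claims_by[[pid]]
          excl <- if (is.null(pc)) c(a = FALSE, b = FALSE) else exclusion_flags(pc, config)
        }
        if ((alg$exclude_a && excl[["a"]]) || (alg$exclude_b && excl[["b"]])) {
          positive <- FALSE
        }
      }
      out[pid, ai] <- positive
    }
  }
  out
}
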