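# Diagnosis-code and specialty classification.
#
# Administrative sources code diagnoses in three dialects: OHIP physician
# billing (a modified ICD-8, three-digit numeric codes), pre-2002 hospital
# abstracts (ICD-9), and post-2002 hospital abstracts (ICD-10). Matching is
# by code *prefix*, case- and dot-insensitive, so "714.0" and "M05.9" match
# the prefixes "714" and "M05".

DX_SYSTEMS <- c("OHIP_DX", "ICD9", "ICD10")
DRUG_CLASSES <- c("DMARD", "BIOLOGIC", "GLUCOCORTICOSTEROID", "NSAID_COXIB", "OTHER")

#' Default code and specialty configuration
#'
#' Returns the configuration used throughout the package to classify diagnosis
#' codes as rheumatoid arthritis (RA), "other rheumatology", or other, to
#' recognise musculoskeletal (MSK) specialists, and to map drug identifiers to
#' therapeutic classes.
#'
#' The RA code sets are the validated ones: OHIP/ICD-9 code 714 and ICD-10
#' M05-M06. The "other rheumatology" sets cover the named conditions
#' (osteoarthritis, gout, polymyalgia rheumatica, seronegative
#' spondyloarthropathy, ankylosing spondylitis, connective tissue disorders,
#' psoriasis, synovitis/tenosynovitis/bursitis, vasculitis); no authoritative
#' code list exists for these in the validation literature, so the concrete
#' prefixes below are implementer-supplied defaults, editable via
#' [read_code_config()] / [write_code_config()] or by modifying the returned
#' list.
#'
#' @return An object of class `ra_code_config`: a list with elements
#'   `ra_prefixes`, `other_rheum_prefixes` (named lists, one character vector
#'   of prefixes per code system), `msk_specialties` (character vector,
#'   lower-case), and `drug_class_map` (named character vector mapping drug
#'   identifiers to one of `r toString(DRUG_CLASSES)`).
#' @examples
#' cfg <- default_code_config()
#' classify_code("M06.0", "ICD10", cfg)
#' @export
default_code_config <- function() {
  other9 <- c(
    "715", # osteoarthritis
    "274", # gout
    "725", # polymyalgia rheumatica
    "720", # ankylosing spondylitis / spondyloarthropathy
    "710", # diffuse connective tissue disease
    "696", # psoriasis / psoriatic arthropathy
    "727", # synovitis, tenosynovitis, bursitis
    "446", "447" # vasculitides
  )
  cfg <- list(
    ra_prefixes = list(
      OHIP_DX = "714",
      ICD9 = "714",
      ICD10 = c("M05", "M06")
    ),
    other_rheum_prefixes = list(
      OHIP_DX = other9,
      ICD9 = other9,
      ICD10 = c(
        "M15", "M16", "M17", "M18", "M19", # osteoarthritis
        "M10",                             # gout
        "M30", "M31",                      # vasculitis
        "M32", "M33", "M34", "M35",        # connective tissue disease, PMR (M35.3)
        "M45", "M46",                      # ankylosing spondylitis / spondyloarthropathy
        "M65", "M70", "M71",               # synovitis / tenosynovitis / bursitis
        "L40"                              # psoriasis
      )
    ),
    msk_specialties = c("rheumatology", "orthopedic surgery", "internal medicine"),
    drug_class_map = c(
      methotrexate = "DMARD", hydroxychloroquine = "DMARD",
      sulfasalazine = "DMARD", leflunomide = "DMARD", gold = "DMARD",
      azathioprine = "DMARD",
      etanercept = "BIOLOGIC", infliximab = "BIOLOGIC", adalimumab = "BIOLOGIC",
      anakinra = "BIOLOGIC",
      prednisone = "GLUCOCORTICOSTEROID",
      methylprednisolone = "GLUCOCORTICOSTEROID",
      triamcinolone = "GLUCOCORTICOSTEROID",
      naproxen = "NSAID_COXIB", ibuprofen = "NSAID_COXIB",
      celecoxib = "NSAID_COXIB", diclofenac = "NSAID_COXIB"
    )
  )
  structure(validate_code_config(cfg), class = "ra_code_config")
}

validate_code_config <- function(cfg) {
  stopifnot(is.list(cfg))
  req <- c("ra_prefixes", "other_rheum_prefixes", "msk_specialties", "drug_class_map")
  missing <- setdiff(req, names(cfg))
  if (length(missing)) {
    stop("code config is missing element(s): ", paste(missing, collapse = ", "))
  }
  for (sys in names(cfg$ra_prefixes)) {
    if (!length(cfg$ra_prefixes[[sys]])) {
      stop("empty RA prefix list for system ", sys)
    }
    ov <- intersect(
      normalize_code(cfg$ra_prefixes[[sys]]),
      normalize_code(cfg$other_rheum_prefixes[[sys]] %||% character())
    )
    if (length(ov)) {
      stop(
        "RA and other-rheumatology prefixes overlap for system ", sys, ": ",
        paste(ov, collapse = ", ")
      )
    }
  }
  cfg$msk_specialties <- normalize_specialty(cfg$msk_specialties)
  bad <- setdiff(unname(cfg$drug_class_map), DRUG_CLASSES)
  if (length(bad)) {
    stop("unknown drug class(es) in drug_class_map: ", paste(unique(bad), collapse = ", "))
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dot- and case-insensitive form used for all prefix matching
normalize_code <- function(x) gsub(".", "", toupper(trimws(x)), fixed = TRUE)

normalize_specialty <- function(x) tolower(trimws(x))

#' Classify diagnosis codes
#'
#' Vectorised over `value`/`system`. A code is `RA` when its normalised form
#' (upper case, dots stripped) starts with any configured RA prefix for its
#' coding system; `OTHER_RHEUM` analogously for the other-rheumatology sets;
#' `OTHER` otherwise. A system with no configured RA prefixes is an error,
#' never silently `OTHER`.
#'
#' @param value Character vector of diagnosis codes (e.g. `"714"`, `"M05.9"`).
#' @param system Character vector (recycled) of coding systems, one of
#'   `"OHIP_DX"`, `"ICD9"`, `"ICD10"`.
#' @param config An `ra_code_config`, see [default_code_config()].
#' @return Character vector in `c("RA", "OTHER_RHEUM", "OTHER")`.
#' @examples
#' classify_code(c("714", "M06.0", "250"), c("OHIP_DX", "ICD10", "ICD9"))
#' @export
classify_code <- function(value, system, config = default_code_config()) {
  if (!length(value)) return(character())
  if (any(!nzchar(trimws(value)) | is.na(value))) {
    stop("diagnosis code values must be non-empty")
  }
  system <- rep_len(as.character(system), length(value))
  unknown <- setdiff(unique(system), names(config$ra_prefixes))
  if (length(unknown)) {
    stop(
      "coding system(s) absent from config: ", paste(unknown, collapse = ", "),
      " (refusing to classify as OTHER)"
    )
  }
  val <- normalize_code(value)
  out <- rep("OTHER", length(value))
  for (sys in unique(system)) {
    idx <- which(system == sys)
    ra <- normalize_code(config$ra_prefixes[[sys]])
    other <- normalize_code(config$other_rheum_prefixes[[sys]] %||% character())
    is_ra <- Reduce(`|`, lapply(ra, function(p) startsWith(val[idx], p)), rep(FALSE, length(idx)))
    out[idx][is_ra] <- "RA"
    if (length(other)) {
      is_or <- Reduce(`|`, lapply(other, function(p) startsWith(val[idx], p)), rep(FALSE, length(idx)))
      out[idx][is_or & !is_ra] <- "OTHER_RHEUM"
    }
  }
  out
}

#' Is a provider specialty a musculoskeletal specialty?
#'
#' Matching is case-insensitive and whitespace-trimmed. Unknown specialties are
#' `FALSE` (not an error): billing data carry many specialty strings and only
#' the configured MSK set matters to the algorithms.
#'
#' @param specialty Character vector of specialty strings.
#' @inheritParams classify_code
#' @return Logical vector.
#' @examples
#' is_msk_specialist(c("rheumatology", "Family Medicine", " Internal Medicine "))
#' @export
is_msk_specialist <- function(specialty, config = default_code_config()) {
  normalize_specialty(specialty) %in% config$msk_specialties
}

#' Read / write a code configuration as JSON
#'
#' @param path File path of the JSON configuration.
#' @return `read_code_config()` returns a validated `ra_code_config`;
#'   `write_code_config()` returns `path` invisibly.
#' @seealso [default_code_config()]; the packaged default lives at
#'   `system.file("extdata", "code_config.json", package = "raclaims")`.
#' @export
read_code_config <- function(path) {
  if (!file.exists(path)) stop("code config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$ra_prefixes <- lapply(cfg$ra_prefixes, as.character)
  cfg$other_rheum_prefixes <- lapply(cfg$other_rheum_prefixes, as.character)
  cfg$drug_class_map <- unlist(cfg$drug_class_map)
  structure(validate_code_config(cfg), class = "ra_code_config")
}

#' @rdname read_code_config
#' @param config An `ra_code_config`.
#' @export
write_code_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
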