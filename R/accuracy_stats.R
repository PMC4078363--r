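# Diagnostic accuracy against the chart-review reference standard:
# confusion tables, sensitivity/specificity/predictive values with binomial
# confidence intervals, lexicographic ranking, and the rendering conventions
# of the published validation tables.

#' Cross-classify predictions against reference labels
#'
#' @param predictions Named logical vector: `TRUE` = classified positive.
#' @param labels Named logical vector: `TRUE` = reference-standard case (see
#'   [apply_reference_definition()]). Must cover exactly the same patient ids.
#' @return An object of class `ra_confusion`: list with integer cells `tp`,
#'   `fp`, `fn`, `tn` (cells sum to the cohort size).
#' @examples
#' confusion_table(
#'   c(a = TRUE, b = FALSE, c = TRUE),
#'   c(a = TRUE, b = TRUE, c = FALSE)
#' )
#' @export
confusion_table <- function(predictions, labels) {
  if (is.null(names(predictions)) || is.null(names(labels))) {
    stop("predictions and labels must be named by patient_id")
  }
  miss_p <- setdiff(names(labels), names(predictions))
  miss_l <- setdiff(names(predictions), names(labels))
  if (length(miss_p) || length(miss_l)) {
    stop(
      "prediction/label key mismatch; missing predictions for: ",
      paste(utils::head(miss_p, 5L), collapse = ", "),
      "; missing labels for: ", paste(utils::head(miss_l, 5L), collapse = ", ")
    )
  }
  lab <- labels[names(predictions)]
  ra_confusion(
    tp = sum(predictions & lab), fp = sum(predictions & !lab),
    fn = sum(!predictions & lab), tn = sum(!predictions & !lab)
  )
}

#' @rdname confusion_table
#' @param tp,fp,fn,tn Non-negative integer cells.
#' @export
ra_confusion <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("confusion cells must be non-negative integers")
  }
  structure(as.list(stats::setNames(as.integer(cells), names(cells))),
            class = "ra_confusion")
}

#' @export
print.ra_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("test+", "test-"), c("case", "non-case")))
  print(m)
  invisible(x)
}

#' Binomial proportion confidence interval
#'
#' The default (and the convention used in the published tables) is the Wald
#' normal approximation, `p +- z * sqrt(p (1-p) / n)`, clipped to `[0, 1]`;
#' Wilson and Clopper-Pearson are available for sensitivity analyses. At
#' `p` of exactly 0 or 1 the Wald interval has zero width.
#'
#' @param p_hat Point estimate(s) in `[0, 1]`.
#' @param denom Denominator(s), >= 1.
#' @param level Confidence level (default 0.95, z = 1.959964).
#' @param method `"wald"`, `"wilson"` or `"clopper-pearson"`.
#' @return Two-column matrix with columns `low`, `high` clipped to `[0, 1]`;
#'   `NA` rows where `p_hat` is `NA` or `denom` is 0.
#' @examples
#' wald_ci(54 / 69, 69) # reproduces the printed 69-88 after percent rounding
#' @export
prop_ci <- function(p_hat, denom, level = 0.95,
                    method = c("wald", "wilson", "clopper-pearson")) {
  method <- match.arg(method)
  stopifnot(level > 0, level < 1)
  k <- max(length(p_hat), length(denom))
  p <- rep_len(as.numeric(p_hat), k)
  n <- rep_len(as.numeric(denom), k)
  z <- stats::qnorm(1 - (1 - level) / 2)
  bad <- is.na(p) | is.na(n) | n < 1
  out <- matrix(NA_real_, k, 2, dimnames = list(NULL, c("low", "high")))
  g <- which(!bad)
  if (!length(g)) return(out)
  if (any(p[g] < 0 | p[g] > 1)) stop("p_hat must be in [0, 1]")
  if (method == "wald") {
    half <- z * sqrt(p[g] * (1 - p[g]) / n[g])
    out[g, ] <- cbind(p[g] - half, p[g] + half)
  } else if (method == "wilson") {
    centre <- (p[g] + z^2 / (2 * n[g])) / (1 + z^2 / n[g])
    half <- z * sqrt(p[g] * (1 - p[g]) / n[g] + z^2 / (4 * n[g]^2)) / (1 + z^2 / n[g])
    out[g, ] <- cbind(centre - half, centre + half)
  } else {
    x <- round(p[g] * n[g])
    lo <- ifelse(x == 0, 0, stats::qbeta((1 - level) / 2, x, n[g] - x + 1))
    hi <- ifelse(x == n[g], 1, stats::qbeta(1 - (1 - level) / 2, x + 1, n[g] - x))
    out[g, ] <- cbind(lo, hi)
  }
  out[, 1] <- pmin(pmax(out[, 1], 0), 1)
  out[, 2] <- pmin(pmax(out[, 2], 0), 1)
  out
}

#' @rdname prop_ci
#' @export
wald_ci <- function(p_hat, denom, level = 0.95) {
  prop_ci(p_hat, denom, level = level, method = "wald")
}

#' Diagnostic accuracy measures for one algorithm
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, PPV
#' `tp/(tp+fp)`, NPV `tn/(fn+tn)`, pre-test prevalence `(tp+fn)/N` and
#' post-test prevalence `(tp+fp)/N`, each with a confidence interval on its
#' own denominator. A zero denominator makes that measure (and its interval)
#' `NA` — "undefined", never 0 or 1 — while the rest of the row is still
#' computed.
#'
#' @param ct An `ra_confusion` (see [confusion_table()]).
#' @param algorithm_id Identifier carried into the output row.
#' @param level,ci_method Passed to [prop_ci()].
#' @return One-row data frame with the cells, the six proportions, and
#'   `<measure>_lo` / `<measure>_hi` bounds.
#' @examples
#' diagnostic_metrics(ra_confusion(tp = 62, fp = 243, fn = 7, tn = 7188))
#' @export
diagnostic_metrics <- function(ct, algorithm_id = NA_character_, level = 0.95,
                               ci_method = "wald") {
  stopifnot(inherits(ct, "ra_confusion"))
  n_total <- ct$tp + ct$fp + ct$fn + ct$tn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  est <- c(
    sensitivity = safe_div(ct$tp, ct$tp + ct$fn),
    specificity = safe_div(ct$tn, ct$fp + ct$tn),
    ppv = safe_div(ct$tp, ct$tp + ct$fp),
    npv = safe_div(ct$tn, ct$fn + ct$tn),
    pre_test_prev = safe_div(ct$tp + ct$fn, n_total),
    post_test_prev = safe_div(ct$tp + ct$fp, n_total)
  )
  den <- c(ct$tp + ct$fn, ct$fp + ct$tn, ct$tp + ct$fp, ct$fn + ct$tn,
           n_total, n_total)
  ci <- prop_ci(est, den, level = level, method = ci_method)
  row <- data.frame(
    algorithm_id = algorithm_id,
    tp = ct$tp, tn = ct$tn, fn = ct$fn, fp = ct$fp,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(est)) {
    nm <- names(est)[i]
    row[[nm]] <- unname(est[i])
    row[[paste0(nm, "_lo")]] <- ci[i, "low"]
    row[[paste0(nm, "_hi")]] <- ci[i, "high"]
  }
  row
}

#' Rank algorithms by the published criterion
#'
#' Stable lexicographic sort on highest PPV, then highest sensitivity, then
#' highest specificity, optionally after dropping rows below a minimum
#' sensitivity. Ties keep input order; undefined (`NA`) PPVs sort last.
#'
#' @param rows Data frame of metric rows ([diagnostic_metrics()] output,
#'   row-bound).
#' @param min_sensitivity Optional filter, a proportion in `[0, 1]`.
#' @return The reordered (and possibly filtered) data frame.
#' @export
rank_algorithms <- function(rows, min_sensitivity = NULL) {
  stopifnot(is.data.frame(rows))
  req <- c("ppv", "sensitivity", "specificity")
  check_columns(rows, req, "metric rows")
  if (!is.null(min_sensitivity)) {
    stopifnot(min_sensitivity >= 0, min_sensitivity <= 1)
    rows <- rows[!is.na(rows$sensitivity) & rows$sensitivity >= min_sensitivity, ,
                 drop = FALSE]
  }
  if (!nrow(rows)) return(rows)
  ord <- order(-rows$ppv, -rows$sensitivity, -rows$specificity, na.last = TRUE)
  rows[ord, , drop = FALSE]
}

# Half-away-from-zero rounding at `digits` decimals. base::round() rounds
# half to even; the published tables round half up (e.g. 68.53 -> 69 via the
# unrounded bound, 0.5 -> 50%). The 1e-9 nudge guards against binary
# representation of exact halves (all inputs here are small rationals).
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Render a proportion the way the published tables print it
#'
#' `"metric"` renders an integer percent; `"prevalence"` renders one decimal
#' place. `NA` renders `"undefined"`.
#'
#' Metric rendering rounds half away from zero in *two stages* — percent to
#' one decimal, then to an integer — because that is the convention the
#' published tables demonstrably used: 7393/7431 = 99.4886% prints as 100
#' (99.49 -> 99.5 -> 100, where direct rounding gives 99) and 52/68 =
#' 76.47% prints as 77. Two-stage rounding reproduces every printed metric
#' in the 43-row reference set; direct rounding fails five rows.
#'
#' @param p Proportion(s) in `[0, 1]` (or `NA`).
#' @param kind `"metric"` or `"prevalence"`.
#' @return Character vector.
#' @examples
#' render_percent(62 / 69, "metric") # "90"
#' render_percent(305 / 7500, "prevalence") # "4.1"
#' @export
render_percent <- function(p, kind = c("metric", "prevalence")) {
  kind <- match.arg(kind)
  out <- rep("undefined", length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("proportions must be in [0, 1]")
  out[ok] <- if (kind == "metric") {
    sprintf("%d", as.integer(round_half_up(round_half_up(p[ok] * 100, 1L))))
  } else {
    sprintf("%.1f", round_half_up(p[ok] * 100, 1L))
  }
  out
}

#' Render a metric with its confidence interval, table style
#' @param p,lo,hi Proportions.
#' @return Strings like `"90 (83-97)"`.
#' @export
render_metric_ci <- function(p, lo, hi) {
  ifelse(
    is.na(p), "undefined",
    paste0(render_percent(p, "metric"), " (", render_percent(lo, "metric"),
           "-", render_percent(hi, "metric"), ")")
  )
}

#' Published validation-study results bundled with the package
#'
#' The 43 confusion tables (and printed accuracy metrics) of the Ontario
#' primary-care RA validation study: 28 algorithms evaluated on 7500 adults
#' (>= 20 y, 69 reference-standard cases) and 15 drug-requiring algorithms on
#' 3426 seniors (>= 65 y, 63 cases). Used by the regression tests that check
#' this package's arithmetic against every printed value, and available as a
#' worked reference set.
#'
#' One printed row ("3 P by any physician in 2 YR", id `p3_2y`) has an FP
#' cell (54) inconsistent with its own row (cells must sum to 7500 and
#' non-cases to 7431; the printed PPV 60, specificity 100 and post-test
#' prevalence 1.2 all imply FP = 36). With
#' `correct_inconsistencies = TRUE` (default) the reconciled FP is returned;
#' the as-printed value is kept in `fp_printed`.
#'
#' @param correct_inconsistencies Replace the one inconsistent FP cell with
#'   its reconciled value.
#' @return Data frame, one row per published algorithm: `subset`
#'   (`adults`/`seniors`), `algorithm_id`, `dsl` (grammar form, see
#'   [parse_algorithm()]), `label` (published row label), cells `tp`, `tn`,
#'   `fn`, `fp`, `fp_printed`, and the printed metric renderings
#'   (`post_prev`, `sens`, `sens_lo`, `sens_hi`, ..., `npv_hi`).
#' @export
published_algorithm_results <- function(correct_inconsistencies = TRUE) {
  path <- system.file("extdata", "published_results.csv", package = "raclaims")
  df <- as.data.frame(data.table::fread(path))
  df$fp_printed <- df$fp
  if (correct_inconsistencies) {
    i <- df$algorithm_id == "p3_2y"
    df$fp[i] <- 36L
  }
  df
}
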