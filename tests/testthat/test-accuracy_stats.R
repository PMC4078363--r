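test_that("confusion tables cross-classify and guard their keys", {
  # degenerate all-negative classifier on 2 cases / 3 non-cases
  pred <- stats::setNames(rep(FALSE, 5), letters[1:5])
  lab <- stats::setNames(c(TRUE, TRUE, FALSE, FALSE, FALSE), letters[1:5])
  ct <- confusion_table(pred, lab)
  expect_identical(unclass(ct)[c("tp", "fp", "fn", "tn")],
                   list(tp = 0L, fp = 0L, fn = 2L, tn = 3L))
  # perfect classifier
  perf <- confusion_table(lab, lab)
  expect_identical(perf$fp + perf$fn, 0L)
  expect_error(confusion_table(pred[1:4], lab), "key mismatch.*e")
  expect_error(confusion_table(unname(pred), lab), "named")
  expect_error(ra_confusion(-1, 0, 0, 0), "non-negative")
})

test_that("diagnostic metrics reproduce the printed worked examples", {
  m <- diagnostic_metrics(ra_confusion(tp = 62, fp = 243, fn = 7, tn = 7188))
  expect_equal(m$sensitivity, 62 / 69)
  expect_identical(render_percent(m$sensitivity, "metric"), "90")
  expect_identical(render_percent(m$specificity, "metric"), "97")
  expect_identical(render_percent(m$ppv, "metric"), "20")
  expect_identical(render_percent(m$post_test_prev, "prevalence"), "4.1")

  m2 <- diagnostic_metrics(ra_confusion(tp = 53, fp = 12, fn = 16, tn = 7419))
  expect_equal(m2$ppv, 53 / 65)
  expect_identical(render_percent(m2$ppv, "metric"), "82")
  expect_identical(render_percent(m2$sensitivity, "metric"), "77")
})

test_that("zero denominators yield undefined measures, not zeros or errors", {
  m <- diagnostic_metrics(ra_confusion(tp = 0, fp = 0, fn = 5, tn = 5))
  expect_true(is.na(m$ppv))
  expect_true(is.na(m$ppv_lo))
  expect_identical(m$sensitivity, 0)
  expect_identical(render_percent(m$ppv, "metric"), "undefined")
})

test_that("sensitivity times its denominator returns tp exactly", {
  set.seed(88)
  for (i in 1:50) {
    cells <- sample(0:400, 4, replace = TRUE)
    ct <- ra_confusion(cells[1], cells[2], cells[3], cells[4])
    m <- diagnostic_metrics(ct)
    if (!is.na(m$sensitivity)) {
      expect_equal(m$sensitivity * (ct$tp + ct$fn), ct$tp)
    }
    if (!is.na(m$specificity)) {
      expect_equal(m$specificity * (ct$fp + ct$tn), ct$tn)
    }
  }
})

rhu <- function(x) floor(x + 0.5 + 1e-9) # half-up, matching the render rules

test_that("Wald intervals reproduce printed intervals and behave", {
  expect_identical(as.integer(rhu(100 * wald_ci(54 / 69, 69))), c(69L, 88L))
  expect_identical(as.integer(rhu(100 * wald_ci(53 / 65, 65))), c(72L, 91L))
  # boundary estimates clip to zero-width intervals
  expect_identical(unname(wald_ci(1, 50)[1, ]), c(1, 1))
  expect_identical(unname(wald_ci(0, 50)[1, ]), c(0, 0))
  # hand evaluation of the closed form: 0.5 +- 1.96 * 0.05
  expect_identical(as.integer(rhu(100 * wald_ci(0.5, 100))), c(40L, 60L))
  # width shrinks monotonically with the denominator
  widths <- vapply(c(10, 50, 250, 1250), function(n) diff(wald_ci(0.3, n)[1, ]), 1)
  expect_true(all(diff(widths) < 0))
  expect_true(all(is.na(prop_ci(0.5, 0))))
  # alternative methods stay inside [0,1] and bracket the estimate
  for (meth in c("wilson", "clopper-pearson")) {
    ci <- prop_ci(0.9, 30, method = meth)
    expect_true(ci[1, 1] <= 0.9 && ci[1, 2] >= 0.9)
    expect_true(ci[1, 1] >= 0 && ci[1, 2] <= 1)
  }
})

test_that("ranking is lexicographic on (PPV, sensitivity, specificity) and stable", {
  rows <- data.frame(
    algorithm_id = c("a", "b", "c"),
    ppv = c(0.5, 0.5, 0.6),
    sensitivity = c(0.9, 0.8, 0.1),
    specificity = c(0.9, 0.9, 0.9)
  )
  expect_identical(rank_algorithms(rows)$algorithm_id, c("c", "a", "b"))
  expect_identical(rank_algorithms(rows[2, ])$algorithm_id, "b")
  expect_identical(rank_algorithms(rows, min_sensitivity = 0.75)$algorithm_id,
                   c("a", "b"))
  # ties preserve input order
  tie <- data.frame(algorithm_id = c("x", "y"), ppv = 0.4, sensitivity = 0.4,
                    specificity = 0.4)
  expect_identical(rank_algorithms(tie)$algorithm_id, c("x", "y"))
})

test_that("the published adult table ranks 1-H-ever first by the stated rule", {
  pub <- published_algorithm_results()
  adults <- pub[pub$subset == "adults", ]
  rows <- do.call(rbind, lapply(seq_len(nrow(adults)), function(i) {
    diagnostic_metrics(
      ra_confusion(adults$tp[i], adults$fp[i], adults$fn[i], adults$tn[i]),
      algorithm_id = adults$algorithm_id[i]
    )
  }))
  expect_identical(rank_algorithms(rows)$algorithm_id[1], "h1")
})

test_that("render_percent follows the published two-stage convention", {
  expect_identical(render_percent(0.8986, "metric"), "90")
  expect_identical(render_percent(0.04067, "prevalence"), "4.1")
  expect_identical(render_percent(0.5, "metric"), "50")
  # the two-stage cases that motivated the convention
  expect_identical(render_percent(7393 / 7431, "metric"), "100")
  expect_identical(render_percent(52 / 68, "metric"), "77")
  expect_identical(render_percent(NA_real_, "metric"), "undefined")
  expect_error(render_percent(1.2), "must be in")
  expect_identical(render_metric_ci(0.8986, 0.8273, 0.9698), "90 (83-97)")
})
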