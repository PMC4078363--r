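# raclaims

Rule-based rheumatoid arthritis (RA) case ascertainment in health
administrative claims, with the diagnostic-accuracy machinery used to
validate such case definitions against a chart-review reference standard.

## The problem

Health administrative databases — physician billing claims, hospital
discharge abstracts, emergency department records, pharmacy claims — are a
standard resource for chronic-disease surveillance, but they record billing
codes, not verified diagnoses. Before an RA "case definition" such as

> *[1 hospitalization RA code] OR [3 physician RA diagnosis codes with ≥ 1
> by a musculoskeletal specialist within 2 years]*

can be used for research, its accuracy must be measured against a reference
standard built from chart review. For each candidate algorithm *A* and
reference label, the cohort is cross-classified into TP/FP/FN/TN and
summarised as

- sensitivity = TP / (TP + FN), specificity = TN / (FP + TN),
- PPV = TP / (TP + FP), NPV = TN / (FN + TN),
- pre-test prevalence = (TP + FN) / N, post-test prevalence = (TP + FP) / N,

each with a 95% Wald confidence interval, and algorithms are ranked by
highest PPV, then sensitivity, then specificity.

`raclaims` implements the whole workflow for an Ontario-style data
environment (OHIP billing with one ICD-8-style diagnosis per claim; ICD-9
hospital abstracts before 2002 and ICD-10 after; pharmacy claims observed
from age 65):

- **Claims model** — strict, validating readers/writers for a five-CSV
  cohort layout (patients, physician claims, hospital/ER records, drug
  claims, reference labels).
- **Code sets** — prefix-based, dot-insensitive classification of diagnosis
  codes (RA: OHIP/ICD-9 714, ICD-10 M05–M06) and MSK-specialist matching.
- **Algorithm engine** — a small declarative grammar for case definitions
  (`"1H | 3P(spec>=1)/2y"`, `"2P(gap>=56d,rx>=1)/1y"`, `"... excl(A,B)"`)
  and an exact evaluator: counts of distinct RA-coded encounter dates inside
  sliding windows, minimum gaps, specialist and drug-claim co-requirements,
  hospital/ER branches, and the Case A / Case B exclusion rules.
- **Accuracy statistics** — confusion tables, the six measures above with
  Wald (default), Wilson or Clopper–Pearson intervals, table-faithful
  rendering, ranking, plus the 43 published validation rows bundled as a
  regression reference.
- **Synthetic cohort generator** — a seeded simulator of an
  EMRALD-like primary-care validation cohort (0.9% / 1.8% lifetime RA
  prevalence by age stratum, 86% specialist involvement, calibrated coding
  and miscoding rates, drug exposures) so every stage is testable without
  access to real linked health data.
- **Pipeline** — `simulate → evaluate → rank → compare` as R functions and a
  CLI (`inst/exec/raclaims`).

## Worked example

Reproduce a published-style accuracy row from its confusion cells:

```r
library(raclaims)
m <- diagnostic_metrics(ra_confusion(tp = 62, fp = 243, fn = 7, tn = 7188))
render_metric_ci(m$sensitivity, m$sensitivity_lo, m$sensitivity_hi)
#> "90 (83-97)"        # sensitivity of the "1 P ever" definition
render_percent(m$post_test_prev, "prevalence")
#> "4.1"
```

Simulate a validation cohort (7500 adults + 2000 seniors) and rank five
classic case definitions on it:

```r
coh   <- generate_cohort(cohort_params(seed = 42))
truth <- apply_reference_definition(coh, "DEFINITE_ONLY")
algs  <- default_algorithms()[c("h1", "p1", "p2_1y", "p3_spec_2y", "h1_p3_spec_2y")]
pred  <- evaluate_cohort(coh, algs, subset = "adults")
rows  <- do.call(rbind, lapply(colnames(pred), function(a)
  diagnostic_metrics(confusion_table(pred[, a], truth[rownames(pred)]), algorithm_id = a)))
rank_algorithms(rows)
```

which prints (formatted):

```
     algorithm  TP  FP FN       sens          spec         ppv
            h1  35   3 90 28 (20-36) 100 (100-100) 92 (84-100)
    p3_spec_2y  96  11 29 77 (69-84) 100 (100-100)  90 (84-96)
 h1_p3_spec_2y 105  14 20 84 (78-90) 100 (100-100)  88 (82-94)
         p2_1y 111  93 14 89 (83-94)    99 (99-99)  54 (48-61)
            p1 116 325  9 93 (88-97)    97 (96-97)  26 (22-30)
```

Read it the way a validation study would: hospitalization codes alone (`h1`)
are highly predictive but miss most cases; a single billing code ever (`p1`)
finds nearly everyone but one positive in four is real; requiring three
codes with specialist involvement (`p3_spec_2y`) trades sensitivity for PPV;
adding the hospital branch (`h1_p3_spec_2y`) buys back sensitivity at almost
no PPV cost — the structure that made that algorithm the published choice.

The same pipeline from the shell:

```sh
inst/exec/raclaims simulate --seed 42 --out cohort/
inst/exec/raclaims evaluate --cohort cohort/ --mode definite_only --subset seniors --out results/
inst/exec/raclaims rank --results results/results.json --min-sens 75
```

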