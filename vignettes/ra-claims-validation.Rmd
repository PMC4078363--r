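---
title: "Methods: rule-based RA case ascertainment and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based RA case ascertainment and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raclaims)
```

## The procedure

A *case-ascertainment algorithm* is a deterministic rule over one patient's
coded administrative events that classifies the patient as having rheumatoid
arthritis (RA) or not. `raclaims` represents an algorithm as an OR of
clauses plus optional exclusion rules. A clause demands `n` RA-coded
encounter dates from one source — physician billing (`P`), inpatient
hospital (`H`), or emergency department (`ER`) — inside a temporal window,
with optional refinements: a minimum gap between counted dates, a
musculoskeletal (MSK) specialist among the counted encounters, and a
co-occurring RA-drug pharmacy claim. Validation then scores each algorithm's
output against a chart-review reference standard with the standard 2×2
machinery (sensitivity, specificity, PPV, NPV, pre-/post-test prevalence,
95% CIs) and ranks algorithms by PPV, then sensitivity, then specificity.

## Engine semantics and why they were chosen

The published row labels ("3 P with ≥ 1 P by a specialist in 2 YR") leave
several operational questions open. The conventions below are this package's
definitions; each is a deliberate choice, and tests pin all of them.

**Code matching.** RA is OHIP/ICD-9 prefix `714` and ICD-10 `M05`–`M06`,
matched case- and dot-insensitively on the normalised code (`"M05.9"`
matches `"M05"`). A coding system missing from the configuration is an
error, never silently "not RA". The "other rheumatology" sets used by the
exclusion rules have no published code list; the shipped defaults
(osteoarthritis 715/M15–M19, gout 274/M10, polymyalgia rheumatica 725,
ankylosing spondylitis/spondyloarthropathy 720/M45–M46, connective-tissue
disease 710/M32–M35, psoriasis 696/L40, synovitis/tenosynovitis/bursitis
727/M65–M71, vasculitis 446–447/M30–M31) are implementer-supplied and fully
overridable in `code_config.json`.

**Distinct dates, not claims.** Billing commonly emits several claims per
encounter, so same-day RA claims collapse to one qualifying date ("2 P"
plainly means two encounters). `count_same_day = TRUE` restores claim-level
counting for sensitivity analyses. A date is specialist-flagged if *any* RA
claim that day carries an MSK specialty (rheumatology, orthopedic surgery,
internal medicine; matching is case/whitespace-insensitive).

**Windows.** "1 YR" = 365 days, "8 weeks" = 56 days; the span is inclusive
(`D_n − D_1 ≤ window`). Windows slide freely: any qualifying subset
anywhere in the 20-year observation period counts, consistent with the
published observation that varying window duration mattered little. The
minimum gap applies between consecutive counted dates, which for the printed
two-claim case is exactly "≥ 8 weeks apart". The specialist requirement must
be met by one of the *n counted* dates, not by any specialist claim ever —
the natural reading of "3 P with ≥ 1 P by a specialist".

**Exact search.** `window_satisfied()` returns the earliest qualification
date via a longest minimum-gap-chain dynamic program over candidate last
dates (with a reachability variant for the specialist case). It is exact; an
independent brute-force oracle that enumerates every date subset verifies it
on tens of thousands of random patients in the test suite. The two code
paths share nothing but the data preparation.

**Drug co-requirement.** Pharmacy claims are only observed from age 65, so a
drug-requiring clause is `FALSE` for anyone younger at the index date
(2010-12-31, configurable). Under "in W YR" all required events — the `n`
billing dates *and* ≥ 1 claim for a DMARD, biologic, or glucocorticosteroid
— must fit inside one interval of length `W` (co-occurrence, the natural
reading of "2 P AND ≥ 1 Rx in 1 YR"); under "ever" the drug claim may fall
anywhere in the observation window.

**Exclusions.** The published description is one sentence; the package's
operational reading is: Case A triggers when an other-rheumatology billing
code appears *strictly after the last* RA billing code; Case B when a
rheumatology-specialty claim carrying a non-RA code appears *on or after the
first* RA billing code. Both scan physician billing only, and a patient with
no RA billing (e.g. a hospital-only positive) triggers neither. These
anchors are documented as interpretation, not as published fact.

**Monotonicity.** These semantics make tightening monotone — raising `n`,
shrinking the window, adding a gap/specialist/drug requirement, or enabling
exclusions can only shrink the positive set, and adding an OR clause can
only grow it — which the property tests assert on whole simulated cohorts.

## Statistical conventions

**Confidence intervals.** The published intervals are reproduced by the Wald
normal approximation `p ± 1.959964·√(p(1−p)/n)` clipped to [0, 1] (e.g.
54/69 → 69–88 after rounding), so Wald is the default; Wilson and
Clopper–Pearson are available via `ci_method`. A zero denominator makes a
measure and its interval "undefined" — never 0 or 100. A handful of printed
interval bounds differ by one point from every standard method (e.g. 15/69
prints an upper bound of 32 where Wald, Wilson and exact all give 31–33
variants other than 32); the package does not chase those.

**Rounding.** Metric percentages are rendered by *two-stage* half-up
rounding — percent to one decimal, then to an integer — because the
published tables demonstrably used it: 7393/7431 = 99.4886% prints as 100
(99.49 → 99.5 → 100) and 52/68 = 76.47% prints as 77. Two-stage rounding
reproduces every printed metric in the bundled 43-row reference set; direct
one-stage rounding fails five of them. Prevalences render at one decimal.
Exact halves are nudged by 1e-9 before flooring to defeat binary
representation of decimal halves; all rendered quantities are small
rationals, so the nudge can never cross a true non-half boundary.

**Reference data.** One published row ("3 P by any physician in 2 YR") has
an FP cell of 54 that contradicts its own row (cells must sum to 7500,
non-cases to 7431, and the printed PPV 60 / specificity 100 / post-test
prevalence 1.2 all imply FP = 36). `published_algorithm_results()` returns
the reconciled cell by default and keeps the as-printed value in
`fp_printed`.

## The synthetic cohort: a stated world

No patient-level data accompany the validation study, so the generator
emulates its cohort structure. The defaults *are* the stated world and are
not tuned to test outcomes:

| parameter | default | provenance |
|---|---|---|
| cohort | 7500 adults ≥ 20 y + 2000 seniors ≥ 65 y | published design |
| lifetime RA prevalence | 0.9% (20–64), 1.8% (≥ 65) | published results |
| possible-RA labels | +0.4% of non-cases | published 0.9% → 1.3% shift |
| specialist involvement | 86% of cases | published chart review |
| case ever RA-coded in billing | 90% | 62/69 printed cells |
| minimally coded cases (1 code ever) | 7% of coded | 58/62 with ≥ 2 codes |
| non-case ever miscoded | 3.3% | 243/7431 printed cells |
| case RA hospitalization | 22% (ER 3%) | 15/69, 16/69 printed cells |
| senior-case drug exposure | DMARD 80%, steroid 61%, biologic 17%, NSAID 77% | published Table of clinical characteristics |
| case sex | 64% female | published results |
| ages | N(49, 17) truncated to [20, 98]; extra seniors N(76.3, 6.8) | published means/SDs |

Parameters with no published counterpart were fixed once at values a claims
analyst would call realistic and documented here: active-care RA visit rate
4/year over an episode of 2–8 years; a 30% chance of one late RA code after
the active episode (so lifetime cases not under current care exist — the
mechanism behind the lower sensitivity in primary-care populations);
background billing at 1 visit/year drawn from common primary-care codes
including osteoarthritis (which is what makes exclusion Case A bite);
miscodes clustered in a one-year episode with count 1 + Poisson(0.35) and a
20% MSK-specialty share. One seeded RNG stream drives everything;
generation restores the caller's RNG state and identical parameters give
byte-identical CSVs.

The prevalence parameters are applied per age stratum as specified (0.9%
to ages 20–64, 1.8% to 65+), so the realized all-adult prevalence is
slightly above 0.9% — the published 0.9% is the marginal over all adults.
The spec's own binomial-band check at n = 7500 passes under this reading.

**What a green test establishes — and what it does not.** The simulator
reproduces marginal coding rates and the qualitative accuracy structure
(specificity ≈ 97–100%, PPV rising steeply with specialist and multi-code
requirements, PPV but not sensitivity responding to prevalence, sensitivity
falling when possible-RA patients are regrouped as cases). It does not
reproduce the published confusion tables row-for-row: real comorbidity
structure, physician-level clustering, referral dynamics and coding drift
are out of scope. The published field results (e.g. the optimal algorithm's
78/100/78/100 row) are therefore covered by the printed-cell regression
tests, not by simulation; claims about real-data performance are outside
what this package can establish.

## Numerical and degenerate-input choices

Dates are ISO 8601, arithmetic in whole days; events outside the
1991-04-01 – 2011-03-31 observation window are load-time errors, never
silently dropped. An unsatisfiable clause (window < gap·(n−1)) warns at
construction and at evaluation. Empty event streams classify negative under
every algorithm; empty algorithm lists evaluate to an empty result table,
exit 0. Ranking ties preserve input order (stable sort); undefined PPVs sort
last. The seniors analysis subset is age ≥ 65 at the index date; because the
generator oversamples seniors as a separate stratum, the "adults" subset
(≥ 20) includes them, mirroring a stratified validation sample rather than a
population age structure.

## Known limitations

- Exclusion-rule anchors and the drug co-occurrence window are interpretive
  (documented above, switchable in code) — the source material underdefines
  them.
- The engine's incident-date output is the qualification date only; no
  incident-vs-prevalent adjudication is attempted.
- The ranking implements only the stated lexicographic rule; the published
  "optimal" algorithm was additionally chosen on coverage grounds the rule
  does not capture, so reproducing that qualitative choice is not asserted.
- The simulator's event streams are two-phase renewal processes with uniform
  dates; intra-episode spacing carries no clinical signal.
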