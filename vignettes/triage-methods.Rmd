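---
title: "Methods: triage decision trees, accuracy statistics and the synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triage decision trees, accuracy statistics and the synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptt24)
```

## The problem

Primary major-incident triage prioritises casualties at the scene using
checks simple enough to apply in seconds: ambulation, airway/breathing,
conscious level, respiratory rate (RR) and heart rate (HR). The clinically
meaningful reference standard is *need for a life-saving intervention*
(LSI): a casualty is truly Priority One (P1) if they went on to receive at
least one intervention from a consensus-derived LSI list. A triage tool is
then an imperfect binary test for that need, and its quality is summarised
by sensitivity, specificity, positive predictive value (PPV) and the
diagnostic odds ratio (DOR), with undertriage = 1 − sensitivity and
overtriage = 1 − PPV as the operational readings.

This package implements three tools as pure functions of a casualty
record, the LSI ground-truth definition, the accuracy statistics, and a
synthetic cohort generator that makes the whole pipeline verifiable
without access to governed trauma-registry data.

## The decision trees

All three tools share one engine (`classify_with_thresholds()`) and one
step order, short-circuiting at the first step that fires:

1. catastrophic external haemorrhage → P1 (tools that use this step);
2. walking → P3;
3. not breathing after airway opening → DEAD;
4. conscious-level trigger → P1;
5. RR below the lower bound → P1;
6. RR at/above the upper bound → P1;
7. HR at/above the bound → P1;
8. otherwise P2.

The tools differ only in data (`inst/extdata/tool_thresholds.yaml`):

| tool | haemorrhage step | conscious rule | RR band passes | HR passes |
|---|---|---|---|---|
| MPTT | no | GCS < 14 | 12–21 | < 100 |
| MPTT-24 | yes | not Alert (AVPU) | 12–23 | < 100 |
| UK Military Sieve | yes | none | 10–29 | ≤ 120 |

Boundary conventions matter at exactly the integers tests pin: the MPTT
family flags *at* its upper RR threshold (≥ 22 / ≥ 24) and at HR ≥ 100;
the Sieve passes its band inclusively (10–29) and flags only at pulse
> 120 (the doctrinal "121 or more"). The MPTT-24's threshold of 24 exists
for arithmetic, not physiology: 24 is divisible by 4 and 6, so a
15-second breath count × 4 (or 10-second × 6, `rr_from_count()`) decides
the step, roughly halving measurement time per casualty.

Conscious level: on the AVPU scale the split is Alert vs not-Alert; the
legacy GCS formulation puts the same split at GCS < 14 (the
alert/voice-responsive division falls at a median GCS of 13). `is_alert()`
bridges the two: AVPU wins when both are recorded (the MPTT-24 is defined
on AVPU), GCS ≥ 14 substitutes when only GCS is present, and a record
violating A ⇔ GCS ≥ 14 raises a data-quality warning, not an error. No
V/P/U sub-level is ever invented from a GCS value — only the binary split
the tools need.

Because the engine is threshold-parameterised, setting the MPTT-24 block
to `rr_high = 22`, `conscious_rule = "gcs_lt_14"` and the haemorrhage step
off reproduces the MPTT record-for-record; the test suite asserts this,
and asserts by exhaustive RR scan that with all else non-triggering the
two tools disagree only at RR ∈ {22, 23}.

### Missing data

A record that reaches a step whose observation is missing is governed by
`missing_policy`: `"exclude"` (default — the record's category is `NA` and
is counted, mirroring registry analyses restricted to first-recorded
hospital values), `"normal"` (the step does not fire) or `"abnormal"` (it
fires). A record decided before the gap is reached is unaffected.
`assume_non_ambulant = TRUE` (the default in `triage_report()`) forces
`can_walk = FALSE`, the appropriate reading for hospital registry
populations whose inclusion criteria make ambulant presentation
uninformative.

## Accuracy statistics

`confusion()` collapses categories to P1 vs not-P1 (DEAD and P3 are both
negative — the dichotomy is strictly "P1 or not"). Proportions carry
Wilson score 95% intervals (no continuity correction; well-behaved near 0
and 1, and checked in tests against `prop.test(correct = FALSE)`). The
DOR carries a Woolf log-normal interval. Two prevalence-free identities
are exposed directly because they let published operating points be
audited without counts:

- `dor_from_rates(sens, spec)` = [sens/(1−sens)]·[spec/(1−spec)], equal to
  (TP·TN)/(FP·FN) on any table (property-tested);
- `ppv_from_rates(sens, spec, prev)` = sens·prev / (sens·prev +
  (1−spec)(1−prev)), equal to TP/(TP+FP) on tables consistent with those
  rates (property-tested).

Paired tools are compared with `mcnemar_p1()`. "Correct" means the
binary-collapsed call matches LSI truth, not raw category agreement. The
statistic is (b−c)²/(b+c) on 1 df without continuity correction — at
registry sample sizes the correction is immaterial — switching to the
two-sided exact binomial when b + c < 25. One subtlety the tests document:
the *corrected* chi-square is the approximation that tracks the exact
binomial (agreement within 0.0023 across b + c in 25–100, exhaustive
scan); the uncorrected default can differ from the exact p by up to 0.16
near b = c, which is precisely why the exact branch exists for small
discordance.

`number_needed_to_assess(delta)` = 1/delta converts a sensitivity gap
into its clinical reading: how many genuine P1 casualties are assessed
before the less sensitive tool misses one more.

## The synthetic cohorts

`generate_cohort()` draws truth Bernoulli(p1_prevalence), then physiology
from class-conditional distributions: integer RR and HR from discretised
normals truncated at 0 (clinical measurement granularity; exact threshold
semantics), Bernoulli alert/haemorrhage/apnoea/walking flags, V/P/U
sub-levels for non-alert casualties. True-P1 records receive a sentinel
LSI code so ground truth flows through `is_priority_one()` end-to-end
rather than bypassing it.

`analytic_operating_point()` enumerates the discrete joint distribution
and pushes every support point through the *actual* classifier, giving
the exact population sensitivity/specificity that cohort estimates must
converge to — the oracle behind the convergence tests (3-SE band at
n = 10⁵).

Two presets emulate the coarse structure of the registry populations such
tools are evaluated on: `"jttr-like"` (military, P1 prevalence 47.6%) and
`"tarn-like"` (civilian, 19.5%). Registries publish no physiology
distributions, so the class-conditional parameters were *fitted* once
(weighted least squares on closed-form flag rates, L-BFGS-B under
clinically plausible box constraints, MPTT weighted highest) so the
MPTT's analytic operating point lands near the published registry values:

```{r presets}
analytic_operating_point("jttr-like", "mptt")   # published ~ (0.699, 0.653)
analytic_operating_point("tarn-like", "mptt")   # published ~ (0.578, 0.715)
```

The parameters are frozen in the preset YAML files with these caveats
stated there too. What the presets are *not*: reconstructions of registry
data. Fields are independent given class (real physiology is correlated
within casualty — a shocked casualty is tachycardic *and* tachypnoeic *and*
obtunded together), RR/HR marginals are unimodal normals (real registry
RR is heaped at round numbers), and no mechanism-of-injury, injury-severity
or mortality structure is modelled. Consequently, passing tests show the
*software* computes the right quantities on populations with known
operating points; they say nothing about how any tool performs on real
casualties. Exact simultaneous matching of all five published tool
operating points is impossible under class-conditional independence with
normal margins; the MPTT points sit within ±5 percentage points and the
other tools land close (Sieve within ~3 points, bare-RR thresholds within
~4).

## Numerical and design choices

- **Problem sizes.** Property tests use cohorts of 10³–10⁵ and the
  convergence checks n = 10⁵; enumeration grids trim probability mass
  below 10⁻¹⁰ and renormalise. These sizes give Monte-Carlo standard
  errors of ~0.2 percentage points, well inside every band asserted.
- **Degenerate inputs.** Zero metric margins raise an `undefined-metric`
  error from the metric functions but are caught and flagged (`notes`
  column) by `triage_report()`, so degenerate cohorts still report.
  b + c = 0 in McNemar returns p = 1. Boundary rates (0 or 1) are
  rejected by `dor_from_rates()`; `ppv_from_rates()` accepts perfect
  specificity (PPV 1).
- **Ties and ordering.** Step order only matters where DEAD/P3 interact
  with P1 (a walking casualty with catastrophic haemorrhage is P1 under
  the MPTT-24, P3 under the MPTT); tests pin those records explicitly.
- **Determinism.** All randomness flows from a single seed argument;
  `generate_cohort()` restores the caller's RNG state. Reports are
  invariant to record order.
- **LSI vocabulary.** Shipped as an editable JSON file and matched by
  exact code. Registries encode interventions differently, so the
  auditable data file — not code — is the single source of truth; the
  packaged list is an editorial reconstruction of the consensus LSI
  definition, and any computation is unchanged under a user-supplied
  registry.

## Limitations

Beyond the simulator limitations above: the package evaluates tools on
first-recorded observations as given (no modelling of prehospital vs
hospital physiology availability), implements no secondary triage, no
paediatric tools and no injury-severity scoring, and the published
operating points quoted in comments are for orientation only — nothing in
the package claims to reproduce registry results, only the arithmetic
identities among published numbers (which the acceptance script
recomputes) and the internal consistency of its own machinery.
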