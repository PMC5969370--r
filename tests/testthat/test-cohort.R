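test_that("generated cohorts are reproducible and hit the preset prevalence", {
  a <- generate_cohort("jttr-like", seed = 101, n = 10000)
  b <- generate_cohort("jttr-like", seed = 101, n = 10000)
  expect_identical(a, b)
  # observed P1 fraction within 3 SE of the preset prevalence
  se <- sqrt(0.476 * (1 - 0.476) / 10000)
  expect_lt(abs(mean(a$truth) - 0.476), 3 * se)
  tarn <- generate_cohort("tarn-like", seed = 102, n = 10000)
  se_t <- sqrt(0.195 * (1 - 0.195) / 10000)
  expect_lt(abs(mean(tarn$truth) - 0.195), 3 * se_t)
})

test_that("truth is injected through the LSI pathway, not around it", {
  co <- generate_cohort("jttr-like", seed = 7, n = 2000)
  expect_equal(is_priority_one(co), co$truth)
  # non-P1 records carry no interventions at all
  expect_true(all(lengths(co$interventions[!co$truth]) == 0))
})

test_that("point-mass populations give the expected degenerate operating points", {
  # all non-P1 mass at RR 16 / HR 80, alert, no haemorrhage: specificity 1
  p <- point_mass_params(p1_rr = 30, p1_hr = 80)
  for (tool in triage_tools()) {
    expect_equal(analytic_operating_point(p, tool)[["specificity"]], 1)
  }
  # all P1 mass at RR 23: the threshold gap is the tools' only disagreement
  p23 <- point_mass_params(p1_rr = 23, p1_hr = 80)
  expect_equal(analytic_operating_point(p23, "mptt")[["sensitivity"]], 1)
  expect_equal(analytic_operating_point(p23, "mptt24")[["sensitivity"]], 0)
})

test_that("enumeration matches Monte-Carlo estimates on an arbitrary population", {
  params <- cohort_params(
    n = 60000, p1_prevalence = 0.4,
    p1 = class_physiology(rr = list(mean = 22, sd = 6),
                          hr = list(mean = 95, sd = 18),
                          alert_prob = 0.8, cathaem_prob = 0.07,
                          apnoea_prob = 0.03),
    not_p1 = class_physiology(rr = list(mean = 17, sd = 4),
                              hr = list(mean = 80, sd = 12),
                              alert_prob = 0.95, cathaem_prob = 0.005)
  )
  co <- generate_cohort(params, seed = 31)
  for (tool in c("mptt", "mptt24", "uk_military_sieve")) {
    op <- analytic_operating_point(params, tool)
    pred <- is_p1(classify_cohort(co, tool))
    n1 <- sum(co$truth)
    n0 <- sum(!co$truth)
    sens_hat <- sum(pred & co$truth) / n1
    spec_hat <- sum(!pred & !co$truth) / n0
    se_sens <- sqrt(op[["sensitivity"]] * (1 - op[["sensitivity"]]) / n1)
    se_spec <- sqrt(op[["specificity"]] * (1 - op[["specificity"]]) / n0)
    expect_lt(abs(sens_hat - op[["sensitivity"]]), 3 * se_sens + 1e-9)
    expect_lt(abs(spec_hat - op[["specificity"]]), 3 * se_spec + 1e-9)
  }
})

test_that("preset MPTT operating points sit near the published registry values", {
  jttr <- analytic_operating_point("jttr-like", "mptt")
  expect_lt(abs(jttr[["sensitivity"]] - 0.699), 0.05)
  expect_lt(abs(jttr[["specificity"]] - 0.653), 0.05)
  tarn <- analytic_operating_point("tarn-like", "mptt")
  expect_lt(abs(tarn[["sensitivity"]] - 0.578), 0.05)
  expect_lt(abs(tarn[["specificity"]] - 0.715), 0.05)
})

test_that("zero missingness yields zero exclusions; missingness yields some", {
  co <- generate_cohort("jttr-like", seed = 55, n = 3000)
  for (tool in triage_tools()) {
    expect_equal(attr(classify_cohort(co, tool), "n_excluded"), 0)
  }
  params <- cohort_preset("jttr-like", n = 3000)
  params$missing_rates[["rr_bpm"]] <- 0.2
  miss <- generate_cohort(params, seed = 56)
  expect_gt(attr(classify_cohort(miss, "mptt24"), "n_excluded"), 0)
})
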