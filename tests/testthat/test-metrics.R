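test_that("confusion collapses categories to P1/not-P1 and counts cells", {
  t1 <- confusion(c("P1", "P2"), c(TRUE, FALSE))
  expect_equal(unlist(t1[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 0L, fn = 0L, tn = 1L))
  t2 <- confusion(c("P3", "P1"), c(TRUE, FALSE))
  expect_equal(c(t2$fn, t2$fp), c(1L, 1L))
  t3 <- confusion("DEAD", TRUE)
  expect_equal(t3$fn, 1L)
  expect_error(confusion(c("P1", "P2"), TRUE), "equal length")
  # NA pairs (exclusions) are dropped and counted
  t4 <- confusion(c("P1", NA, "P2"), c(TRUE, TRUE, FALSE))
  expect_equal(t4$n_excluded, 1L)
  expect_equal(t4$tp + t4$fp + t4$fn + t4$tn, 2L)
})

test_that("sensitivity and friends give Wilson intervals matching prop.test", {
  expect_equal(sensitivity(confusion_table(50, 0, 50, 0))$value, 0.5)
  # counts reconstructed from a 69.9% sensitivity on 1738 positives
  t <- confusion_table(tp = 1215, fp = 0, fn = 523, tn = 1)
  expect_equal(sensitivity(t)$value, 0.699, tolerance = 1e-3)
  z <- confusion_table(tp = 0, fp = 1, fn = 10, tn = 5)
  expect_equal(sensitivity(z)$value, 0)
  expect_equal(sensitivity(z)$ci_low, 0)
  expect_error(sensitivity(confusion_table(0, 5, 0, 5)), "zero margin")

  # Wilson interval against the independent stats::prop.test implementation
  for (case in list(c(8, 10), c(1, 40), c(120, 200), c(0, 15))) {
    ours <- wilson_ci <- sensitivity(confusion_table(case[1], 0,
                                                     case[2] - case[1], 1))
    ref <- prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(c(ours$ci_low, ours$ci_high), as.numeric(ref),
                 tolerance = 1e-8)
  }
})

test_that("Wilson interval always brackets the estimate inside [0, 1]", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(1:500, 1)
    x <- sample(0:n, 1)
    m <- mptt24:::wilson_ci(x, n)
    expect_gte(m[["low"]], 0)
    expect_lte(m[["high"]], 1)
    expect_lte(m[["low"]], x / n + 1e-12)
    expect_gte(m[["high"]], x / n - 1e-12)
  }
})

test_that("DOR from rates matches the count identity and published rows", {
  # identity closure against (tp*tn)/(fp*fn) on random all-positive tables
  set.seed(9)
  for (i in 1:50) {
    cells <- sample(1:500, 4, replace = TRUE)
    t <- confusion_table(cells[1], cells[2], cells[3], cells[4])
    from_counts <- (t$tp * t$tn) / (t$fp * t$fn)
    from_rates <- dor_from_rates(sensitivity(t)$value, specificity(t)$value)
    expect_equal(from_rates, from_counts, tolerance = 1e-10)
    expect_equal(dor(t)$value, from_counts)
  }
  expect_equal(dor_from_rates(0.5, 0.5), 1)
  expect_equal(dor_from_rates(0.699, 0.653), 4.37, tolerance = 0.01)
  expect_equal(dor_from_rates(0.432, 0.937), 11.3, tolerance = 0.01 * 11.3)
  expect_error(dor_from_rates(1, 0.5), "inside")
  expect_error(dor(confusion_table(5, 0, 3, 2)), "zero cell")
})

test_that("Bayes PPV agrees with count-based PPV and handles boundaries", {
  # tables consistent with given rates: ppv_from_rates == tp/(tp+fp)
  set.seed(13)
  for (i in 1:50) {
    cells <- sample(1:500, 4, replace = TRUE)
    t <- confusion_table(cells[1], cells[2], cells[3], cells[4])
    n <- cells[1] + cells[2] + cells[3] + cells[4]
    prev <- (t$tp + t$fn) / n
    expect_equal(
      ppv_from_rates(sensitivity(t)$value, specificity(t)$value, prev),
      ppv(t)$value, tolerance = 1e-10)
  }
  expect_equal(ppv_from_rates(0.7, 1.0, 0.3), 1)
  expect_equal(ppv_from_rates(0.699, 0.653, 0.476), 0.647, tolerance = 0.001)
  expect_error(ppv_from_rates(0.7, 0.6, 0), "prevalence")
})

test_that("undertriage and overtriage are the published complements", {
  expect_equal(overtriage(0.340), 0.660)
  expect_equal(overtriage(0.329), 0.671)
  expect_equal(undertriage(1.0), 0)
  t <- confusion_table(60, 40, 40, 60)
  expect_equal(undertriage(t), 1 - sensitivity(t)$value)
  expect_equal(overtriage(t), 1 - ppv(t)$value)
})

test_that("number needed to assess is the reciprocal sensitivity gap", {
  expect_equal(number_needed_to_assess(0.032), 31.25)
  expect_equal(number_needed_to_assess(0.5), 2)
  expect_equal(number_needed_to_assess(0.01), 100)
  expect_error(number_needed_to_assess(0), "positive")
})
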