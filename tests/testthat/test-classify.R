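cat1 <- function(x) as.character(x)[1]

test_that("MPTT tree follows the sieve structure with GCS/RR/HR triggers", {
  expect_equal(cat1(classify_mptt(make_record(can_walk = TRUE))), "P3")
  expect_equal(cat1(classify_mptt(make_record(breathing = FALSE))), "DEAD")
  # RR >= 22 is P1-positive
  expect_equal(cat1(classify_mptt(make_record(gcs = 15, avpu = NA, rr = 22))),
               "P1")
  expect_equal(cat1(classify_mptt(make_record(gcs = 15, avpu = NA, rr = 16))),
               "P2")
  expect_equal(cat1(classify_mptt(make_record(gcs = 13, avpu = NA))), "P1")
  expect_equal(cat1(classify_mptt(make_record(rr = 11))), "P1")
  expect_equal(cat1(classify_mptt(make_record(hr = 100))), "P1")
  # MPTT has no haemorrhage step: bleeding walker is still P3
  expect_equal(cat1(classify_mptt(make_record(can_walk = TRUE,
                                              cathaem = TRUE))), "P3")
})

test_that("MPTT-24 raises the RR threshold, uses AVPU and adds haemorrhage", {
  # haemorrhage step precedes the walking check
  expect_equal(cat1(classify_mptt24(make_record(cathaem = TRUE,
                                                can_walk = TRUE))), "P1")
  expect_equal(cat1(classify_mptt24(make_record(rr = 23))), "P2")
  expect_equal(cat1(classify_mptt24(make_record(rr = 24))), "P1")
  expect_equal(cat1(classify_mptt24(make_record(avpu = "V"))), "P1")
  expect_equal(cat1(classify_mptt24(make_record(breathing = FALSE))), "DEAD")
  expect_equal(cat1(classify_mptt24(make_record(rr = 11))), "P1")
  expect_equal(cat1(classify_mptt24(make_record(hr = 100))), "P1")
})

test_that("UK Military Sieve uses the 10-29 RR band and pulse > 120", {
  expect_equal(cat1(classify_uk_military_sieve(make_record(rr = 30))), "P1")
  expect_equal(cat1(classify_uk_military_sieve(make_record(rr = 9))), "P1")
  expect_equal(cat1(classify_uk_military_sieve(make_record(rr = 10))), "P2")
  expect_equal(cat1(classify_uk_military_sieve(make_record(rr = 29))), "P2")
  expect_equal(cat1(classify_uk_military_sieve(make_record(hr = 121))), "P1")
  # HR 100 is Sieve-negative though MPTT-positive
  expect_equal(cat1(classify_uk_military_sieve(make_record(hr = 100))), "P2")
  expect_equal(cat1(classify_mptt(make_record(hr = 100))), "P1")
  expect_equal(cat1(classify_uk_military_sieve(make_record(hr = 120))), "P2")
  # no conscious-level step
  expect_equal(cat1(classify_uk_military_sieve(make_record(avpu = "U"))), "P2")
})

test_that("every complete record maps to exactly one category per tool", {
  co <- random_cohort(500, seed = 11)
  for (tool in triage_tools()) {
    out <- classify_cohort(co, tool)
    expect_length(out, 500)
    expect_false(anyNA(out))
    expect_equal(attr(out, "n_excluded"), 0)
    # deterministic: identical on re-run
    expect_equal(out, classify_cohort(co, tool))
  }
})

test_that("MPTT and MPTT-24 disagree only at RR 22 and 23 on the RR axis", {
  # all other observations fixed and non-triggering
  scan <- casualty_cohort(tibble::tibble(
    can_walk = FALSE, breathing_after_airway_opened = TRUE,
    catastrophic_haemorrhage = FALSE, avpu = "A", hr_bpm = 80,
    rr_bpm = 0:60
  ))
  a <- classify_mptt(scan)
  b <- classify_mptt24(scan)
  differs <- which(as.character(a) != as.character(b)) - 1L # RR values
  expect_equal(differs, c(22L, 23L))
  expect_equal(as.character(a)[differs + 1L], c("P1", "P1"))
  expect_equal(as.character(b)[differs + 1L], c("P2", "P2"))
})

test_that("walking casualties escape P1 except via the MPTT-24 haemorrhage step", {
  co <- random_cohort(400, seed = 23)
  walkers <- co[co$can_walk, ]
  expect_false(any(is_p1(classify_mptt(walkers))))
  m24 <- classify_mptt24(walkers)
  expect_equal(is_p1(m24), walkers$catastrophic_haemorrhage)
})

test_that("MPTT-24 engine reduced to MPTT thresholds reproduces MPTT exactly", {
  reduced <- tool_thresholds(rr_low = 12, rr_high = 22, hr_high = 100,
                             conscious_rule = "gcs_lt_14",
                             uses_catastrophic_haemorrhage = FALSE,
                             name = "mptt24-reduced")
  co <- random_cohort(600, seed = 37)
  expect_equal(classify_with_thresholds(co, reduced),
               classify_mptt(co), ignore_attr = TRUE)
})

test_that("missing-data policies exclude, normalise or escalate", {
  rec <- make_record()
  rec$rr_bpm <- NA_integer_
  expect_true(is.na(classify_mptt24(rec)[1]))
  expect_equal(attr(classify_mptt24(rec), "n_excluded"), 1)
  expect_equal(cat1(classify_mptt24(rec, missing_policy = "normal")), "P2")
  expect_equal(cat1(classify_mptt24(rec, missing_policy = "abnormal")), "P1")
  # a record decided before the missing field is reached is not excluded
  early <- make_record(cathaem = TRUE)
  early$rr_bpm <- NA_integer_
  expect_equal(cat1(classify_mptt24(early)), "P1")
  expect_equal(attr(classify_mptt24(early), "n_excluded"), 0)
})

test_that("classify_cohort dispatches, preserves order and rejects unknown tools", {
  expect_error(classify_cohort(make_record(), "salt"), "mptt")
  co <- dplyr::bind_rows(make_record(cathaem = TRUE, can_walk = TRUE),
                         make_record(rr = 23), make_record(avpu = "V"))
  co <- casualty_cohort(co)
  expect_equal(as.character(classify_cohort(co, "mptt24")),
               c("P1", "P2", "P1"))
  empty <- casualty_cohort()
  expect_length(classify_cohort(empty, "mptt24"), 0)
  # assume_non_ambulant overrides the walking observation
  walker <- make_record(can_walk = TRUE, rr = 30)
  expect_equal(cat1(classify_cohort(walker, "mptt24")), "P3")
  expect_equal(cat1(classify_cohort(walker, "mptt24",
                                    assume_non_ambulant = TRUE)), "P1")
})

test_that("bare RR-threshold pseudo-tools classify on RR alone", {
  co <- casualty_cohort(tibble::tibble(rr_bpm = c(21, 22, 23, 24)))
  expect_equal(as.character(classify_cohort(co, "rr22")),
               c("P2", "P1", "P1", "P1"))
  expect_equal(as.character(classify_cohort(co, "rr24")),
               c("P2", "P2", "P2", "P1"))
})
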