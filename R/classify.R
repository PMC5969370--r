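#' Classify casualties with a triage decision tree
#'
#' Runs the shared primary-triage decision tree over a cohort with a given
#' threshold set. Steps are applied in the fixed doctrinal order --
#' catastrophic haemorrhage (if the tool uses it), walking, breathing after
#' airway opening, conscious level, respiratory-rate lower bound,
#' respiratory-rate upper bound, heart rate -- short-circuiting at the first
#' step that fires. A casualty passing every step is P2.
#'
#' Missing data: a record that reaches a step whose observation is missing
#' is handled by `missing_policy`:
#' * `"exclude"` (default) -- the record's category is `NA` and it is
#'   counted in the `n_excluded` attribute of the result (registry-style
#'   analyses exclude records without the needed first-recorded values);
#' * `"normal"` -- the missing observation is assumed unremarkable and the
#'   step does not fire;
#' * `"abnormal"` -- the step fires as if positive.
#'
#' @param cohort A [casualty_cohort()] (or coercible data frame).
#' @param thresholds A [tool_thresholds()] object.
#' @param missing_policy One of `"exclude"`, `"normal"`, `"abnormal"`.
#' @param assume_non_ambulant If `TRUE`, `can_walk` is forced to `FALSE`
#'   for every record before classification (hospital trauma-registry
#'   populations are treated as non-ambulant by construction).
#' @return A factor of triage categories (levels P1, P2, P3, DEAD) with an
#'   `n_excluded` attribute.
#' @export
#' @examples
#' cohort <- casualty_cohort(data.frame(
#'   can_walk = FALSE, breathing_after_airway_opened = TRUE,
#'   catastrophic_haemorrhage = FALSE, avpu = "A", rr_bpm = 24, hr_bpm = 80
#' ))
#' classify_with_thresholds(cohort, tool_thresholds_config()$mptt24)
classify_with_thresholds <- function(cohort, thresholds,
                                     missing_policy = c("exclude", "normal",
                                                        "abnormal"),
                                     assume_non_ambulant = FALSE) {
  missing_policy <- match.arg(missing_policy)
  if (!inherits(cohort, "casualty_cohort")) cohort <- casualty_cohort(cohort)
  stopifnot(inherits(thresholds, "tool_thresholds"))
  n <- nrow(cohort)
  th <- thresholds

  can_walk <- if (assume_non_ambulant) rep(FALSE, n) else cohort$can_walk

  rr <- cohort$rr_bpm
  hr <- cohort$hr_bpm
  conscious_trigger <- switch(
    th$conscious_rule,
    gcs_lt_14 = {
      # GCS is this rule's native input; AVPU bridges A <=> GCS >= 14.
      out <- cohort$gcs_total < 14
      use_avpu <- is.na(cohort$gcs_total) & !is.na(cohort$avpu)
      out[use_avpu] <- cohort$avpu[use_avpu] != "A"
      out
    },
    not_alert = !is_alert(cohort$avpu, cohort$gcs_total),
    none = rep(FALSE, n)
  )
  cmp <- function(x, op, cut) if (op == ">=") x >= cut else x > cut

  # Each step: predicate (NA = observation missing) and outcome when it fires.
  steps <- list(
    list(pred = if (th$uses_catastrophic_haemorrhage)
      cohort$catastrophic_haemorrhage else rep(FALSE, n), outcome = "P1"),
    list(pred = can_walk, outcome = "P3"),
    list(pred = !cohort$breathing_after_airway_opened, outcome = "DEAD"),
    list(pred = conscious_trigger, outcome = "P1"),
    list(pred = rr < th$rr_low, outcome = "P1"),
    list(pred = cmp(rr, th$rr_high_op, th$rr_high), outcome = "P1"),
    list(pred = cmp(hr, th$hr_high_op, th$hr_high), outcome = "P1")
  )

  category <- rep(NA_character_, n)
  decided <- rep(FALSE, n)
  excluded <- rep(FALSE, n)
  for (step in steps) {
    pred <- step$pred
    if (missing_policy == "exclude") {
      excluded <- excluded | (!decided & is.na(pred))
    } else {
      pred[is.na(pred)] <- (missing_policy == "abnormal")
    }
    fires <- !decided & !excluded & !is.na(pred) & pred
    category[fires] <- step$outcome
    decided <- decided | fires
  }
  category[!decided & !excluded] <- "P2"

  out <- triage_category(category)
  attr(out, "n_excluded") <- sum(excluded)
  out
}

#' @rdname classify_tools
#' @export
classify_mptt <- function(cohort, ...) {
  classify_with_thresholds(cohort, .default_thresholds()$mptt, ...)
}

#' Classify a cohort with a named triage tool
#'
#' Convenience wrappers around [classify_with_thresholds()] with the
#' packaged default thresholds: `classify_mptt()` (GCS < 14, RR < 12 or
#' >= 22, HR >= 100), `classify_mptt24()` (catastrophic haemorrhage step,
#' not-Alert on AVPU, RR < 12 or >= 24, HR >= 100) and
#' `classify_uk_military_sieve()` (RR outside 10--29, pulse > 120).
#'
#' @param cohort A [casualty_cohort()] (or coercible data frame).
#' @param ... Passed to [classify_with_thresholds()] (`missing_policy`,
#'   `assume_non_ambulant`).
#' @return A factor of triage categories with an `n_excluded` attribute.
#' @name classify_tools
#' @export
classify_mptt24 <- function(cohort, ...) {
  classify_with_thresholds(cohort, .default_thresholds()$mptt24, ...)
}

#' @rdname classify_tools
#' @export
classify_uk_military_sieve <- function(cohort, ...) {
  classify_with_thresholds(cohort, .default_thresholds()$uk_military_sieve,
                           ...)
}

# Cache the packaged threshold file (read once per session).
.threshold_cache <- new.env(parent = emptyenv())
.default_thresholds <- function() {
  if (is.null(.threshold_cache$defaults)) {
    .threshold_cache$defaults <- tool_thresholds_config()
  }
  .threshold_cache$defaults
}

#' Bare respiratory-rate threshold classifier
#'
#' The single-variable comparator used when studying the upper RR threshold
#' in isolation: P1 if and only if RR >= `threshold` breaths/min; all other
#' casualties are P2. Useful as the `rr22` / `rr24` pseudo-tools in
#' [triage_report()].
#'
#' @inheritParams classify_with_thresholds
#' @param threshold P1 boundary in breaths/min (inclusive).
#' @return A factor of triage categories with an `n_excluded` attribute.
#' @export
classify_rr_threshold <- function(cohort, threshold,
                                  missing_policy = c("exclude", "normal",
                                                     "abnormal")) {
  missing_policy <- match.arg(missing_policy)
  if (!inherits(cohort, "casualty_cohort")) cohort <- casualty_cohort(cohort)
  pred <- cohort$rr_bpm >= threshold
  excluded <- is.na(pred) & missing_policy == "exclude"
  pred[is.na(pred)] <- (missing_policy == "abnormal")
  category <- ifelse(pred, "P1", "P2")
  category[excluded] <- NA_character_
  out <- triage_category(category)
  attr(out, "n_excluded") <- sum(excluded)
  out
}

#' Available tool identifiers
#'
#' @return Character vector of identifiers accepted by [classify_cohort()]
#'   and [triage_report()].
#' @export
triage_tools <- function() {
  c("mptt", "mptt24", "uk_military_sieve", "rr22", "rr24")
}

#' Classify a cohort by tool identifier
#'
#' Dispatches to the named tool. Identifiers: `"mptt"`, `"mptt24"`,
#' `"uk_military_sieve"`, plus the bare-threshold pseudo-tools `"rr22"`
#' and `"rr24"`.
#'
#' @inheritParams classify_with_thresholds
#' @param tool Tool identifier (see [triage_tools()]).
#' @param thresholds Optional named list of [tool_thresholds()] overriding
#'   the packaged defaults for the decision-tree tools.
#' @return A factor of triage categories, order-preserving, with an
#'   `n_excluded` attribute counting missing-data exclusions.
#' @export
classify_cohort <- function(cohort, tool,
                            missing_policy = c("exclude", "normal",
                                               "abnormal"),
                            assume_non_ambulant = FALSE,
                            thresholds = NULL) {
  missing_policy <- match.arg(missing_policy)
  tool <- match.arg(tool, triage_tools())
  if (tool %in% c("rr22", "rr24")) {
    return(classify_rr_threshold(cohort,
                                 threshold = if (tool == "rr22") 22L else 24L,
                                 missing_policy = missing_policy))
  }
  th <- if (is.null(thresholds)) .default_thresholds()[[tool]] else
    thresholds[[tool]]
  if (is.null(th)) stop("No thresholds for tool '", tool, "'", call. = FALSE)
  classify_with_thresholds(cohort, th, missing_policy = missing_policy,
                           assume_non_ambulant = assume_non_ambulant)
}
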