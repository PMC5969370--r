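#' Diagnostic-accuracy report for a set of triage tools
#'
#' Evaluates each requested tool against the LSI ground truth on the same
#' cohort and returns one row per tool: the 2x2 cells, sensitivity,
#' specificity, diagnostic odds ratio and PPV (each with its 95% interval),
#' and the derived undertriage (1 - sensitivity) and overtriage (1 - PPV)
#' rates. Tools include the full decision trees and the bare
#' respiratory-rate pseudo-tools `rr22` / `rr24` that classify on RR alone.
#' Metrics with a zero margin (degenerate cohorts) are returned as `NA`
#' with a note rather than an error.
#'
#' @param cohort A [casualty_cohort()] (or coercible data frame).
#' @param truth Logical true-P1 vector; `NULL` derives it from the
#'   cohort's interventions via [is_priority_one()].
#' @param tools Character vector of tool identifiers (see
#'   [triage_tools()]).
#' @param registry [lsi_registry()] used when deriving `truth`.
#' @param missing_policy,assume_non_ambulant Passed to [classify_cohort()].
#'   `assume_non_ambulant` defaults to `TRUE`: registry-style evaluation
#'   treats all casualties as non-ambulant.
#' @return A tibble, one row per tool, plus attributes `predictions`
#'   (named list of category factors) and `truth`.
#' @export
triage_report <- function(cohort, truth = NULL, tools = triage_tools(),
                          registry = lsi_registry(),
                          missing_policy = "exclude",
                          assume_non_ambulant = TRUE) {
  if (!inherits(cohort, "casualty_cohort")) cohort <- casualty_cohort(cohort)
  stopifnot(length(tools) >= 1)
  tools <- match.arg(tools, triage_tools(), several.ok = TRUE)
  if (is.null(truth)) truth <- is_priority_one(cohort, registry)

  predictions <- lapply(stats::setNames(tools, tools), function(tool) {
    classify_cohort(cohort, tool, missing_policy = missing_policy,
                    assume_non_ambulant = assume_non_ambulant)
  })

  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  rows <- purrr::map2(predictions, names(predictions), function(pred, tool) {
    tab <- confusion(pred, truth)
    sens <- safe(sensitivity(tab))
    spec <- safe(specificity(tab))
    pv <- safe(ppv(tab))
    odds <- safe(dor(tab))
    notes <- character()
    if (is.null(sens)) notes <- c(notes, "sensitivity undefined (no true P1)")
    if (is.null(spec)) notes <- c(notes, "specificity undefined (no true not-P1)")
    if (is.null(pv)) notes <- c(notes, "ppv undefined (no P1 calls)")
    if (is.null(odds)) notes <- c(notes, "dor undefined (zero cell)")
    est <- function(m, field) if (is.null(m)) NA_real_ else m[[field]]
    tibble::tibble(
      tool = tool,
      n = tab$tp + tab$fp + tab$fn + tab$tn,
      n_excluded = tab$n_excluded,
      tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn,
      sensitivity = est(sens, "value"),
      sens_low = est(sens, "ci_low"), sens_high = est(sens, "ci_high"),
      specificity = est(spec, "value"),
      spec_low = est(spec, "ci_low"), spec_high = est(spec, "ci_high"),
      dor = est(odds, "value"),
      dor_low = est(odds, "ci_low"), dor_high = est(odds, "ci_high"),
      ppv = est(pv, "value"),
      ppv_low = est(pv, "ci_low"), ppv_high = est(pv, "ci_high"),
      undertriage = if (is.null(sens)) NA_real_ else 1 - sens$value,
      overtriage = if (is.null(pv)) NA_real_ else 1 - pv$value,
      notes = paste(notes, collapse = "; ")
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "predictions") <- predictions
  attr(out, "truth") <- truth
  out
}

#' Pairwise McNemar comparison matrix
#'
#' Runs [mcnemar_p1()] for every unordered pair of the requested tools on
#' the identical cohort (records excluded by either tool's missing-data
#' handling are dropped pairwise).
#'
#' @inheritParams triage_report
#' @param report Optionally, the result of [triage_report()] on this
#'   cohort; its cached predictions and truth are reused.
#' @return A tibble with columns `tool_a`, `tool_b`, `b`, `c`,
#'   `statistic`, `p_value`, `method`.
#' @export
mcnemar_matrix <- function(cohort = NULL, truth = NULL,
                           tools = triage_tools(),
                           registry = lsi_registry(),
                           missing_policy = "exclude",
                           assume_non_ambulant = TRUE, report = NULL) {
  if (is.null(report)) {
    report <- triage_report(cohort, truth, tools, registry,
                            missing_policy, assume_non_ambulant)
  }
  predictions <- attr(report, "predictions")
  truth <- attr(report, "truth")
  tools <- names(predictions)
  if (length(tools) < 2) {
    return(tibble::tibble(tool_a = character(), tool_b = character(),
                          b = integer(), c = integer(),
                          statistic = numeric(), p_value = numeric(),
                          method = character()))
  }
  pairs <- utils::combn(tools, 2, simplify = FALSE)
  dplyr::bind_rows(lapply(pairs, function(pair) {
    cmp <- mcnemar_p1(predictions[[pair[1]]], predictions[[pair[2]]], truth)
    tibble::tibble(tool_a = pair[1], tool_b = pair[2], b = cmp$b, c = cmp$c,
                   statistic = cmp$statistic, p_value = cmp$p_value,
                   method = cmp$method)
  }))
}

#' Display-format a triage report
#'
#' Rounds for presentation the way triage evaluations are conventionally
#' tabulated: percentages to one decimal place, ratios to two.
#'
#' @param report A [triage_report()] tibble.
#' @return A tibble of formatted strings, one row per tool.
#' @export
format_triage_report <- function(report) {
  pct <- function(v, lo, hi) {
    ifelse(is.na(v), "-",
           sprintf("%.1f%% (%.1f-%.1f)", 100 * v, 100 * lo, 100 * hi))
  }
  tibble::tibble(
    tool = report$tool,
    sensitivity = pct(report$sensitivity, report$sens_low, report$sens_high),
    specificity = pct(report$specificity, report$spec_low, report$spec_high),
    OR = ifelse(is.na(report$dor), "-",
                sprintf("%.2f (%.2f-%.2f)", report$dor, report$dor_low,
                        report$dor_high)),
    PPV = pct(report$ppv, report$ppv_low, report$ppv_high),
    undertriage = ifelse(is.na(report$undertriage), "-",
                         sprintf("%.1f%%", 100 * report$undertriage)),
    overtriage = ifelse(is.na(report$overtriage), "-",
                        sprintf("%.1f%%", 100 * report$overtriage))
  )
}
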