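#' Confusion table for predicted-P1 against true-P1
#'
#' Cross-tabulates the binary collapse of a tool's triage categories (`P1`
#' positive; `P2`, `P3` and `DEAD` negative) against the LSI-defined
#' ground truth. Pairs where either element is `NA` (missing-data
#' exclusions) are dropped and counted.
#'
#' @param predicted Factor/character of triage categories, or a logical
#'   vector of predicted-positive flags.
#' @param truth Logical vector of true P1 status, same length.
#' @return A `confusion_table`: list with integer `tp`, `fp`, `fn`, `tn`
#'   and `n_excluded`.
#' @export
#' @examples
#' confusion(c("P1", "P2", "P3", "P1"), c(TRUE, FALSE, TRUE, FALSE))
confusion <- function(predicted, truth) {
  pred_pos <- if (is.logical(predicted)) predicted else is_p1(predicted)
  if (length(pred_pos) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  keep <- !is.na(pred_pos) & !is.na(truth)
  p <- pred_pos[keep]
  t <- as.logical(truth)[keep]
  confusion_table(tp = sum(p & t), fp = sum(p & !t),
                  fn = sum(!p & t), tn = sum(!p & !t),
                  n_excluded = sum(!keep))
}

#' @rdname confusion
#' @param tp,fp,fn,tn Non-negative cell counts.
#' @param n_excluded Records dropped for missing data.
#' @export
confusion_table <- function(tp, fp, fn, tn, n_excluded = 0L) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(cells >= 0), sum(cells) > 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n_excluded = as.integer(n_excluded)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table>\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("P1", "not-P1"),
                              truth = c("P1", "not-P1")))
  print(m)
  if (x$n_excluded > 0) cat("excluded (missing data):", x$n_excluded, "\n")
  invisible(x)
}

# Wilson score interval for a binomial proportion, no continuity correction.
# Chosen over Wald for its behaviour near 0/1 with the small margins that
# degenerate triage tables produce.
wilson_ci <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Proportion / ratio estimate with confidence interval
#'
#' Light container for a diagnostic metric: point value, 95% interval and
#' the interval method (`"wilson"` for proportions, `"woolf-log"` for odds
#' ratios, `"derived"` where the value is an arithmetic identity of other
#' estimates).
#'
#' @param value Point estimate.
#' @param ci_low,ci_high Interval bounds on the same scale.
#' @param method Interval method label.
#' @param n Denominator (margin size) the estimate is based on.
#' @return A `metric_estimate` list.
#' @export
metric_estimate <- function(value, ci_low = NA_real_, ci_high = NA_real_,
                            method = "derived", n = NA_integer_) {
  if (!is.na(ci_low) && !is.na(ci_high)) {
    stopifnot(ci_low <= value + 1e-12, value <= ci_high + 1e-12)
  }
  structure(list(value = value, ci_low = ci_low, ci_high = ci_high,
                 method = method, n = n),
            class = "metric_estimate")
}

#' @export
print.metric_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%.*f (%.*f-%.*f) [%s]\n", digits, x$value, digits, x$ci_low,
              digits, x$ci_high, x$method))
  invisible(x)
}

proportion_metric <- function(x, n, what) {
  if (n == 0) {
    stop("undefined metric: zero margin for ", what, call. = FALSE)
  }
  ci <- wilson_ci(x, n)
  metric_estimate(x / n, ci[["low"]], ci[["high"]], method = "wilson", n = n)
}

#' Diagnostic accuracy metrics of a confusion table
#'
#' Point estimates with Wilson 95% intervals:
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp),
#' ppv = tp/(tp+fp), npv = tn/(tn+fn). A zero margin is an error
#' (undefined metric), matching the degenerate-cohort semantics of
#' [triage_report()], which flags such cells instead.
#'
#' @param t A [confusion_table()].
#' @return A [metric_estimate()].
#' @export
sensitivity <- function(t) proportion_metric(t$tp, t$tp + t$fn, "sensitivity")

#' @rdname sensitivity
#' @export
specificity <- function(t) proportion_metric(t$tn, t$tn + t$fp, "specificity")

#' @rdname sensitivity
#' @export
ppv <- function(t) proportion_metric(t$tp, t$tp + t$fp, "ppv")

#' @rdname sensitivity
#' @export
npv <- function(t) proportion_metric(t$tn, t$tn + t$fn, "npv")

#' Diagnostic odds ratio
#'
#' `dor()` computes (tp*tn)/(fp*fn) from a confusion table with a Woolf
#' (log-normal) 95% interval; `dor_from_rates()` computes the identical,
#' prevalence-free quantity from a (sensitivity, specificity) pair via
#' `OR = [sens/(1-sens)] * [spec/(1-spec)]` -- the identity that lets a
#' published operating point be converted to its odds ratio without the
#' underlying counts.
#'
#' @param t A [confusion_table()] with all cells positive.
#' @return `dor()`: a [metric_estimate()]; `dor_from_rates()`: a number.
#' @export
dor <- function(t) {
  if (any(c(t$tp, t$fp, t$fn, t$tn) == 0)) {
    stop("diagnostic odds ratio undefined: zero cell", call. = FALSE)
  }
  or <- (t$tp * t$tn) / (t$fp * t$fn)
  se <- sqrt(1 / t$tp + 1 / t$fp + 1 / t$fn + 1 / t$tn)
  z <- stats::qnorm(0.975)
  metric_estimate(or, exp(log(or) - z * se), exp(log(or) + z * se),
                  method = "woolf-log",
                  n = t$tp + t$fp + t$fn + t$tn)
}

#' @rdname dor
#' @param sens,spec Sensitivity and specificity as proportions in (0, 1).
#' @export
#' @examples
#' dor_from_rates(0.699, 0.653)
dor_from_rates <- function(sens, spec) {
  if (any(sens <= 0 | sens >= 1 | spec <= 0 | spec >= 1)) {
    stop("dor_from_rates requires rates strictly inside (0, 1)",
         call. = FALSE)
  }
  (sens / (1 - sens)) * (spec / (1 - spec))
}

#' Positive predictive value from rates and prevalence
#'
#' Bayes identity for the predictive value of a positive triage call:
#' `PPV = sens*prev / (sens*prev + (1-spec)*(1-prev))`. Unlike sensitivity
#' and specificity, PPV depends on the P1 prevalence of the population the
#' tool is deployed into.
#'
#' @param sens,spec Sensitivity and specificity as proportions in (0, 1)
#'   (`spec = 1` is allowed and gives PPV 1).
#' @param prevalence True-P1 prevalence in (0, 1).
#' @return PPV as a proportion.
#' @export
#' @examples
#' ppv_from_rates(0.699, 0.653, prevalence = 0.476)
ppv_from_rates <- function(sens, spec, prevalence) {
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop("prevalence must be strictly inside (0, 1)", call. = FALSE)
  }
  if (any(sens <= 0 | sens > 1 | spec < 0 | spec > 1)) {
    stop("rates outside (0, 1]", call. = FALSE)
  }
  sens * prevalence / (sens * prevalence + (1 - spec) * (1 - prevalence))
}

#' Undertriage and overtriage
#'
#' Undertriage is the probability that a genuine P1 casualty is missed:
#' `1 - sensitivity`. Overtriage is the proportion of P1 calls that are
#' wrong: `1 - PPV`. Both accept either a [confusion_table()] or a bare
#' proportion (the corresponding sensitivity or PPV).
#'
#' @param t A [confusion_table()], or a proportion.
#' @return A proportion.
#' @export
#' @examples
#' overtriage(0.340) # a tool with PPV 34.0% overtriages 66.0% of its calls
undertriage <- function(t) {
  1 - (if (inherits(t, "confusion_table")) sensitivity(t)$value else t)
}

#' @rdname undertriage
#' @export
overtriage <- function(t) {
  1 - (if (inherits(t, "confusion_table")) ppv(t)$value else t)
}

#' Number needed to assess per additional undertriage
#'
#' When one tool's sensitivity is lower than another's by
#' `delta_sensitivity`, `1 / delta_sensitivity` genuine P1 casualties must
#' be assessed before the less sensitive tool misses one additional
#' casualty -- the clinical cost of a sensitivity trade-off.
#'
#' @param delta_sensitivity Positive sensitivity difference (proportion).
#' @return Number of genuine P1 casualties per additional undertriage.
#' @export
#' @examples
#' number_needed_to_assess(0.032)
number_needed_to_assess <- function(delta_sensitivity) {
  if (any(delta_sensitivity <= 0)) {
    stop("delta_sensitivity must be positive", call. = FALSE)
  }
  1 / delta_sensitivity
}
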