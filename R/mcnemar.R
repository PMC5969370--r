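#' McNemar test between two paired triage tools
#'
#' Compares two tools evaluated on the identical casualties. "Correct" for
#' a record means the tool's binary-collapsed call (P1 vs not-P1) matches
#' the LSI ground truth; the test uses only the discordant pairs, `b`
#' (A correct, B wrong) and `c` (A wrong, B correct). The chi-square
#' statistic is `(b - c)^2 / (b + c)` on 1 df without continuity correction
#' (immaterial at registry sample sizes); when `b + c` is below
#' `exact_threshold` the two-sided exact binomial test of `b` successes in
#' `b + c` trials at probability 1/2 is used instead. No discordance
#' (`b + c = 0`) gives p = 1.
#'
#' @param pred_a,pred_b Triage category vectors (or logical P1 flags) from
#'   the two tools, same records in the same order.
#' @param truth Logical true-P1 status.
#' @param exact_threshold Switch to the exact binomial below this `b + c`.
#' @param correct Apply the continuity correction to the chi-square
#'   statistic.
#' @return A `paired_comparison`: list with `b`, `c`, `statistic`,
#'   `p_value`, `method`.
#' @export
#' @examples
#' truth <- rep(c(TRUE, FALSE), 50)
#' a <- ifelse(truth, "P1", "P2")       # perfect tool
#' b <- rep("P2", 100)                  # never calls P1
#' mcnemar_p1(a, b, truth)
mcnemar_p1 <- function(pred_a, pred_b, truth, exact_threshold = 25,
                       correct = FALSE) {
  pa <- if (is.logical(pred_a)) pred_a else is_p1(pred_a)
  pb <- if (is.logical(pred_b)) pred_b else is_p1(pred_b)
  if (length(pa) != length(pb) || length(pa) != length(truth)) {
    stop("pred_a, pred_b and truth must have equal length", call. = FALSE)
  }
  keep <- !is.na(pa) & !is.na(pb) & !is.na(truth)
  correct_a <- pa[keep] == truth[keep]
  correct_b <- pb[keep] == truth[keep]
  mcnemar_from_counts(b = sum(correct_a & !correct_b),
                      c = sum(!correct_a & correct_b),
                      exact_threshold = exact_threshold, correct = correct)
}

#' @rdname mcnemar_p1
#' @param b,c Discordant-pair counts.
#' @export
mcnemar_from_counts <- function(b, c, exact_threshold = 25, correct = FALSE) {
  stopifnot(b >= 0, c >= 0)
  n_disc <- b + c
  if (n_disc == 0) {
    out <- list(b = 0L, c = 0L, statistic = NA_real_, p_value = 1,
                method = "no-discordance")
  } else if (n_disc < exact_threshold) {
    # Two-sided exact binomial: sum of tail probabilities no larger than
    # the observed one, under Bin(b + c, 1/2).
    dens <- stats::dbinom(0:n_disc, n_disc, 0.5)
    p <- sum(dens[dens <= stats::dbinom(b, n_disc, 0.5) * (1 + 1e-7)])
    out <- list(b = as.integer(b), c = as.integer(c),
                statistic = NA_real_, p_value = min(1, p),
                method = "exact-binomial")
  } else {
    stat <- if (correct) max(0, abs(b - c) - 1)^2 / n_disc else
      (b - c)^2 / n_disc
    out <- list(b = as.integer(b), c = as.integer(c), statistic = stat,
                p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                method = if (correct) "chi-square-corrected" else
                  "chi-square")
  }
  structure(out, class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> b = %d, c = %d, %s", x$b, x$c, x$method))
  if (!is.na(x$statistic)) cat(sprintf(", chi-sq = %.3f", x$statistic))
  cat(sprintf(", p = %.4g\n", x$p_value))
  invisible(x)
}
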