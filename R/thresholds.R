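#' Load triage-tool threshold configurations
#'
#' Thresholds are data, not code: each tool is a block in a YAML file giving
#' the shared decision-tree engine its boundaries (see the packaged
#' `tool_thresholds.yaml` for the conventions and citations). Re-running the
#' MPTT-24 engine with `rr_high = 22`, `conscious_rule = "gcs_lt_14"` and the
#' haemorrhage step off reproduces the MPTT exactly.
#'
#' @param path Path to a YAML threshold file; `NULL` loads the packaged
#'   defaults for `mptt`, `mptt24` and `uk_military_sieve`.
#' @return Named list of `tool_thresholds` objects.
#' @export
#' @examples
#' th <- tool_thresholds_config()
#' th$mptt24$rr_high
tool_thresholds_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tool_thresholds.yaml", package = "mptt24")
  }
  raw <- yaml::read_yaml(path)
  lapply(raw, function(block) do.call(tool_thresholds, block))
}

#' Construct a single tool's threshold set
#'
#' @param rr_low P1 if respiratory rate < `rr_low` (breaths/min).
#' @param rr_high Upper respiratory-rate boundary (breaths/min).
#' @param rr_high_op `">="` (MPTT family: P1 at the boundary) or `">"`
#'   (Sieve: boundary still passes).
#' @param hr_high Heart-rate boundary (beats/min).
#' @param hr_high_op `">="` or `">"`, as for `rr_high_op`.
#' @param conscious_rule `"gcs_lt_14"`, `"not_alert"` or `"none"`.
#' @param uses_catastrophic_haemorrhage Does the tree open with a
#'   catastrophic external haemorrhage step?
#' @param name Display name.
#' @param citation Provenance note carried through to reports.
#' @return A `tool_thresholds` list.
#' @export
tool_thresholds <- function(rr_low, rr_high, hr_high,
                            conscious_rule = c("gcs_lt_14", "not_alert",
                                               "none"),
                            uses_catastrophic_haemorrhage = FALSE,
                            rr_high_op = ">=", hr_high_op = ">=",
                            name = "custom", citation = "") {
  conscious_rule <- match.arg(conscious_rule)
  stopifnot(rr_low > 0, rr_high > 0, hr_high > 0,
            rr_low < rr_high,
            rr_high_op %in% c(">=", ">"), hr_high_op %in% c(">=", ">"))
  structure(list(name = name, rr_low = as.integer(rr_low),
                 rr_high = as.integer(rr_high), rr_high_op = rr_high_op,
                 hr_high = as.integer(hr_high), hr_high_op = hr_high_op,
                 conscious_rule = conscious_rule,
                 uses_catastrophic_haemorrhage =
                   isTRUE(uses_catastrophic_haemorrhage),
                 citation = citation),
            class = "tool_thresholds")
}

#' @export
print.tool_thresholds <- function(x, ...) {
  cat(sprintf(
    "<tool_thresholds> %s: %sRR < %d or RR %s %d, HR %s %d, conscious rule %s\n",
    x$name,
    if (x$uses_catastrophic_haemorrhage) "cat. haemorrhage step; " else "",
    x$rr_low, x$rr_high_op, x$rr_high, x$hr_high_op, x$hr_high,
    x$conscious_rule))
  invisible(x)
}
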