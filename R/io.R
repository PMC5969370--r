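#' Read casualty records from CSV
#'
#' Expects a header row; columns are matched by name, with an optional
#' `schema` mapping from your file's column names to the canonical ones
#' (registry exports vary, so the mapping is configuration, not position).
#' The `interventions` column holds delimiter-separated code lists; empty
#' cells are missing values. Rows violating record invariants (GCS outside
#' 3--15, unknown AVPU level, negative rates) are not loaded: they are
#' collected into a rejects tibble (attribute `rejects`, columns `row`,
#' `reason`) and reported.
#'
#' @param path CSV file path.
#' @param schema Named character vector: `c(canonical_name = "file_column")`.
#' @param intervention_sep Separator inside the `interventions` column.
#' @return A [casualty_cohort()] with a `rejects` attribute.
#' @export
read_casualties <- function(path, schema = NULL, intervention_sep = ";") {
  if (!file.exists(path)) stop("cannot read casualty file: ", path,
                               call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw)) {
        stop("schema column not in file: ", schema[[canon]], call. = FALSE)
      }
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  known <- c("id", "age_years", "can_walk", "catastrophic_haemorrhage",
             "breathing_after_airway_opened", "rr_bpm", "hr_bpm",
             "gcs_total", "avpu", "interventions", "truth")
  raw <- raw[, intersect(names(raw), known), drop = FALSE]
  if (nrow(raw) == 0) {
    out <- casualty_cohort(raw)
    attr(out, "rejects") <- tibble::tibble(row = integer(),
                                           reason = character())
    return(out)
  }
  for (col in intersect(c("can_walk", "catastrophic_haemorrhage",
                          "breathing_after_airway_opened", "truth"),
                        names(raw))) {
    raw[[col]] <- parse_flexible_logical(raw[[col]])
  }
  for (col in intersect(c("age_years", "rr_bpm", "hr_bpm", "gcs_total"),
                        names(raw))) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  if ("interventions" %in% names(raw)) {
    raw$interventions <- parse_intervention_codes(raw$interventions,
                                                  sep = intervention_sep)
  }
  rejects <- casualty_problems(tibble::as_tibble(raw))
  if (nrow(rejects) > 0) {
    message(nrow(rejects), " row(s) rejected; see attr(., 'rejects')")
    raw <- raw[-unique(rejects$row), , drop = FALSE]
  }
  truth <- raw[["truth"]]
  raw$truth <- NULL
  out <- casualty_cohort(raw)
  if (!is.null(truth)) out$truth <- truth
  attr(out, "rejects") <- rejects
  out
}

parse_flexible_logical <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Write casualty records to CSV
#'
#' Inverse of [read_casualties()]: the interventions list-column is
#' flattened to a delimiter-separated string, missing values become empty
#' cells. `write_casualties()` then `read_casualties()` round-trips valid
#' records.
#'
#' @param cohort A [casualty_cohort()].
#' @param path Output CSV path.
#' @param intervention_sep Separator for the interventions column.
#' @return `path`, invisibly.
#' @export
write_casualties <- function(cohort, path, intervention_sep = ";") {
  flat <- tibble::as_tibble(cohort)
  flat$interventions <- format_intervention_codes(flat$interventions,
                                                  sep = intervention_sep)
  readr::write_csv(flat, path, na = "")
  invisible(path)
}

#' End-to-end tool comparison on a synthetic cohort
#'
#' The full pipeline in one call: generate (or load) a cohort, derive LSI
#' ground truth, classify with every requested tool, and assemble the
#' evaluation table plus the pairwise McNemar matrix. A run manifest
#' (preset, seed, n, tool identifiers, package version) is attached so a
#' run can be reproduced exactly.
#'
#' @param preset Preset name or [cohort_params()] for [generate_cohort()];
#'   ignored when `cohort` is supplied.
#' @param n Cohort size.
#' @param seed Integer seed for cohort generation.
#' @param tools Tool identifiers to evaluate.
#' @param cohort Optionally, an existing cohort (with a `truth` column or
#'   interventions to derive it from).
#' @param out_dir If non-`NULL`, writes `evaluation.csv`,
#'   `mcnemar.csv` and `manifest.json` there.
#' @param ... Passed to [triage_report()].
#' @return List with `report`, `mcnemar` and `manifest`.
#' @export
#' @examples
#' res <- run_compare("jttr-like", n = 2000, seed = 42)
#' format_triage_report(res$report)
run_compare <- function(preset = "jttr-like", n = 10000, seed = 1,
                        tools = triage_tools(), cohort = NULL,
                        out_dir = NULL, ...) {
  if (is.null(cohort)) {
    cohort <- generate_cohort(preset, seed = seed, n = n)
  }
  truth <- if ("truth" %in% names(cohort)) cohort$truth else NULL
  report <- triage_report(cohort, truth = truth, tools = tools, ...)
  pairs <- mcnemar_matrix(report = report)
  manifest <- list(
    preset = if (is.character(preset)) preset else preset$name,
    n = nrow(cohort), seed = seed, tools = tools,
    package_version = as.character(utils::packageVersion("mptt24"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(report, file.path(out_dir, "evaluation.csv"))
    readr::write_csv(pairs, file.path(out_dir, "mcnemar.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(report = report, mcnemar = pairs, manifest = manifest)
}
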