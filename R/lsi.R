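#' Load a life-saving-intervention (LSI) registry
#'
#' The LSI registry is the vocabulary of intervention codes whose receipt
#' defines a true Priority One casualty. The default registry shipped with
#' the package reconstructs the consensus-derived LSI list used in the
#' major-incident literature; because registries encode interventions
#' differently, the registry is deliberately an editable data file
#' (JSON or YAML, entries `{code, label}`) and matching is by exact code.
#'
#' @param path Path to a JSON or YAML registry file; `NULL` loads the
#'   packaged default.
#' @return An `lsi_registry`: a list with character vector `codes` and a
#'   named character vector `labels` (names are codes).
#' @export
#' @examples
#' reg <- lsi_registry()
#' head(reg$codes)
lsi_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lsi_registry.json", package = "mptt24")
  }
  if (!file.exists(path)) stop("LSI registry file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  entries <- raw$interventions
  if (is.null(entries)) entries <- raw
  if (is.data.frame(entries)) {
    codes <- as.character(entries$code)
    labels <- as.character(entries$label)
  } else {
    codes <- vapply(entries, function(e) as.character(e$code), character(1))
    labels <- vapply(entries, function(e) as.character(e$label), character(1))
  }
  if (length(codes) == 0) stop("LSI registry is empty", call. = FALSE)
  if (anyDuplicated(codes)) stop("LSI registry codes must be unique",
                                 call. = FALSE)
  structure(list(codes = codes, labels = stats::setNames(labels, codes),
                 path = path),
            class = "lsi_registry")
}

#' @export
print.lsi_registry <- function(x, ...) {
  cat("<lsi_registry> ", length(x$codes), " intervention codes (",
      x$path, ")\n", sep = "")
  invisible(x)
}

#' Priority One ground truth from received interventions
#'
#' A casualty is truly Priority One (P1) if they received one or more
#' life-saving interventions from the registry list. An empty intervention
#' set is a valid negative; codes outside the registry are ignored.
#'
#' @param interventions A list of character vectors of intervention codes
#'   (one element per casualty), or a `casualty_cohort` tibble.
#' @param registry An [lsi_registry()]; default is the packaged vocabulary.
#' @return Logical vector: `TRUE` where the casualty received at least one
#'   registry intervention.
#' @export
#' @examples
#' is_priority_one(list(c("intubation"), character(), c("aspirin")))
is_priority_one <- function(interventions, registry = lsi_registry()) {
  if (inherits(interventions, "data.frame")) {
    interventions <- interventions$interventions
  }
  stopifnot(inherits(registry, "lsi_registry"))
  vapply(interventions,
         function(codes) any(codes %in% registry$codes),
         logical(1))
}

# "a|b|c" -> list(c("a","b","c")); empty cells -> character(0). Used when
# reading interventions from flat CSV columns.
parse_intervention_codes <- function(x, sep = ";") {
  lapply(as.character(x), function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character())
    trimws(strsplit(cell, sep, fixed = TRUE)[[1]])
  })
}

# Inverse of parse_intervention_codes, for CSV output.
format_intervention_codes <- function(codes, sep = ";") {
  vapply(codes, paste, character(1), collapse = sep)
}
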