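#' Construct and validate a casualty cohort
#'
#' A casualty cohort is a tibble with one row per casualty and the columns
#' every triage tool reads. All observation columns are optional per record
#' (`NA` means "not recorded"); the constructor adds any missing columns,
#' coerces types and enforces range invariants.
#'
#' Columns:
#' * `id` -- character identifier (generated if absent);
#' * `age_years` -- non-negative number;
#' * `can_walk` -- logical, ambulatory at assessment;
#' * `catastrophic_haemorrhage` -- logical, exsanguinating external
#'   haemorrhage (tourniquet / haemostatic-dressing territory);
#' * `breathing_after_airway_opened` -- logical; `FALSE` means apnoeic even
#'   after simple airway opening;
#' * `rr_bpm` -- respiratory rate, breaths/min, non-negative integer;
#' * `hr_bpm` -- heart rate, beats/min, non-negative integer;
#' * `gcs_total` -- Glasgow Coma Scale total, 3--15;
#' * `avpu` -- conscious level on the AVPU scale, one of `"A"`, `"V"`,
#'   `"P"`, `"U"`;
#' * `interventions` -- list-column of character vectors of intervention
#'   codes received (possibly empty).
#'
#' When both `gcs_total` and `avpu` are present they are cross-checked
#' against the conventional bridge `A <=> GCS >= 14`; a violation raises a
#' data-quality warning (the AVPU value still wins in [is_alert()]), never
#' an error.
#'
#' @param data A data frame with any subset of the columns above.
#' @return A validated tibble of class `casualty_cohort`.
#' @export
#' @examples
#' casualty_cohort(data.frame(rr_bpm = c(16, 28), hr_bpm = c(80, 120)))
casualty_cohort <- function(data = NULL) {
  if (is.null(data)) data <- tibble::tibble()
  data <- tibble::as_tibble(data)
  n <- nrow(data)

  if (!"id" %in% names(data)) data$id <- sprintf("c%04d", seq_len(max(n, 0)))
  data$id <- as.character(data$id)

  defaults <- list(
    age_years = NA_real_, can_walk = NA, catastrophic_haemorrhage = NA,
    breathing_after_airway_opened = NA, rr_bpm = NA_integer_,
    hr_bpm = NA_integer_, gcs_total = NA_integer_, avpu = NA_character_
  )
  for (col in names(defaults)) {
    if (!col %in% names(data)) data[[col]] <- rep(defaults[[col]], n)
  }
  if (!"interventions" %in% names(data)) {
    data$interventions <- rep(list(character()), n)
  } else if (!is.list(data$interventions)) {
    data$interventions <- parse_intervention_codes(data$interventions)
  }
  data$interventions <- lapply(data$interventions, function(x) {
    if (length(x) == 0) character() else unique(as.character(x[!is.na(x)]))
  })

  for (col in c("can_walk", "catastrophic_haemorrhage",
                "breathing_after_airway_opened")) {
    data[[col]] <- as.logical(data[[col]])
  }
  for (col in c("rr_bpm", "hr_bpm", "gcs_total")) {
    data[[col]] <- as.integer(round(as.numeric(data[[col]])))
  }
  data$age_years <- as.numeric(data$age_years)
  data$avpu <- toupper(as.character(data$avpu))
  data$avpu[data$avpu %in% c("", "NA")] <- NA_character_

  problems <- casualty_problems(data)
  if (nrow(problems) > 0) {
    stop("Invalid casualty records:\n",
         paste(sprintf("  row %d: %s", problems$row, problems$reason),
               collapse = "\n"), call. = FALSE)
  }

  check_avpu_gcs_consistency(data)

  front <- c("id", "age_years", "can_walk", "catastrophic_haemorrhage",
             "breathing_after_airway_opened", "rr_bpm", "hr_bpm",
             "gcs_total", "avpu", "interventions")
  data <- data[, c(front, setdiff(names(data), front))]
  class(data) <- c("casualty_cohort", class(data))
  data
}

# Range/level violations, one row per problem: row index + reason. Tolerates
# absent columns (read_casualties screens raw rows before defaults exist).
casualty_problems <- function(data) {
  probs <- list()
  note <- function(rows, reason) {
    if (any(rows, na.rm = TRUE)) {
      probs[[length(probs) + 1]] <<- tibble::tibble(
        row = which(rows), reason = reason
      )
    }
  }
  gcs <- data[["gcs_total"]]
  avpu <- data[["avpu"]]
  rr <- data[["rr_bpm"]]
  hr <- data[["hr_bpm"]]
  age <- data[["age_years"]]
  if (!is.null(gcs)) note(!is.na(gcs) & (gcs < 3 | gcs > 15),
                          "gcs_total outside [3, 15]")
  if (!is.null(avpu)) note(!is.na(avpu) & !avpu %in% c("A", "V", "P", "U"),
                           "avpu not one of A/V/P/U")
  if (!is.null(rr)) note(!is.na(rr) & rr < 0, "rr_bpm negative")
  if (!is.null(hr)) note(!is.na(hr) & hr < 0, "hr_bpm negative")
  if (!is.null(age)) note(!is.na(age) & age < 0, "age_years negative")
  if (length(probs) == 0) {
    return(tibble::tibble(row = integer(), reason = character()))
  }
  dplyr::arrange(dplyr::bind_rows(probs), .data$row)
}

# AVPU vs GCS bridge check: A should pair with GCS >= 14. Disagreement is a
# data-quality warning only; AVPU takes precedence downstream.
check_avpu_gcs_consistency <- function(data) {
  both <- !is.na(data$avpu) & !is.na(data$gcs_total)
  clash <- both & ((data$avpu == "A") != (data$gcs_total >= 14))
  if (any(clash)) {
    warning(sum(clash), " record(s) where avpu and gcs_total disagree with ",
            "the A <=> GCS >= 14 bridge; avpu takes precedence",
            call. = FALSE)
  }
  invisible(sum(clash))
}

#' Is the casualty alert?
#'
#' The binary conscious-level split used by the triage tools. On the AVPU
#' scale "alert" is level `A`; the legacy GCS formulation puts the same
#' split at GCS >= 14 (the division between "alert" and "responds to voice"
#' falls at a median GCS of 13, so GCS < 14 is the not-alert side). When
#' both observations are present AVPU wins, since the MPTT-24 is defined on
#' AVPU and GCS is the legacy input.
#'
#' @param avpu Character vector of AVPU levels (`"A"`, `"V"`, `"P"`, `"U"`)
#'   or `NA`; alternatively a `casualty_cohort`, in which case `gcs` is
#'   ignored and taken from the cohort.
#' @param gcs Integer vector of GCS totals (3--15) or `NA`.
#' @return Logical vector; `NA` where neither observation is available.
#' @export
#' @examples
#' is_alert(avpu = c("A", "V", NA), gcs = c(NA, NA, 13))
is_alert <- function(avpu = NULL, gcs = NULL) {
  if (inherits(avpu, "data.frame")) {
    gcs <- avpu$gcs_total
    avpu <- avpu$avpu
  }
  n <- max(length(avpu), length(gcs))
  if (is.null(avpu)) avpu <- rep(NA_character_, n)
  if (is.null(gcs)) gcs <- rep(NA_integer_, n)
  out <- avpu == "A"
  use_gcs <- is.na(avpu) & !is.na(gcs)
  out[use_gcs] <- gcs[use_gcs] >= 14
  out
}

#' Respiratory rate from a partial breath count
#'
#' Primary triage rarely affords a full-minute count: a 15-second count
#' times four (or a 10-second count times six) gives breaths/min. Raising
#' the MPTT's upper threshold from 22 to 24 makes it divisible by four and
#' six, which is what makes these short counts usable.
#'
#' @param breath_count Non-negative integer count of breaths observed.
#' @param window_seconds Counting window; one of 10, 15, 30, 60.
#' @return Respiratory rate in breaths/min (integer).
#' @export
#' @examples
#' rr_from_count(6, 15) # 24
#' rr_from_count(4, 10) # 24
rr_from_count <- function(breath_count, window_seconds) {
  if (!all(window_seconds %in% c(10, 15, 30, 60))) {
    stop("window_seconds must be one of 10, 15, 30, 60", call. = FALSE)
  }
  if (any(breath_count < 0 | breath_count != round(breath_count))) {
    stop("breath_count must be a non-negative integer", call. = FALSE)
  }
  as.integer(breath_count * (60 / window_seconds))
}
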