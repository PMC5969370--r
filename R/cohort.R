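#' Class-conditional physiology specification
#'
#' Describes the distribution of one truth class (P1 or not-P1) in a
#' synthetic cohort. Respiratory and heart rate are integer-valued: either
#' a discretised normal (`list(mean =, sd =)`, rounded to integers and
#' truncated at 0, matching clinical measurement granularity and exact
#' threshold semantics) or an explicit categorical distribution
#' (`list(values =, probs =)`).
#'
#' @param rr,hr Distribution specs as above (breaths/min, beats/min).
#' @param alert_prob Probability the casualty is AVPU `A`.
#' @param cathaem_prob Probability of catastrophic external haemorrhage.
#' @param apnoea_prob Probability of not breathing after airway opening.
#' @param walking_prob Probability of being ambulatory; defaults to 0,
#'   the non-ambulant assumption appropriate to hospital trauma-registry
#'   populations.
#' @param vpu_probs Probabilities of `V`, `P`, `U` given not alert.
#' @return A `class_physiology` list.
#' @export
class_physiology <- function(rr, hr, alert_prob, cathaem_prob = 0,
                             apnoea_prob = 0, walking_prob = 0,
                             vpu_probs = c(0.5, 0.3, 0.2)) {
  probs <- c(alert_prob, cathaem_prob, apnoea_prob, walking_prob)
  stopifnot(all(probs >= 0 & probs <= 1), length(vpu_probs) == 3,
            abs(sum(vpu_probs) - 1) < 1e-8)
  structure(list(rr = rr, hr = hr, alert_prob = alert_prob,
                 cathaem_prob = cathaem_prob, apnoea_prob = apnoea_prob,
                 walking_prob = walking_prob, vpu_probs = vpu_probs),
            class = "class_physiology")
}

# Resolve a distribution spec to an explicit (values, probs) pair over
# non-negative integers. Discretised-normal mass below 1e-10 is trimmed
# and the rest renormalised.
discrete_dist <- function(spec, support_max = 300L) {
  if (!is.null(spec$values)) {
    values <- as.integer(spec$values)
    probs <- as.numeric(spec$probs)
    stopifnot(length(values) == length(probs), all(probs >= 0),
              all(values >= 0))
    s <- sum(probs)
    stopifnot(abs(s - 1) < 1e-6)
    return(list(values = values, probs = probs / s))
  }
  stopifnot(!is.null(spec$mean), !is.null(spec$sd), spec$sd > 0)
  k <- 0:support_max
  p <- stats::pnorm(k + 0.5, spec$mean, spec$sd) -
    stats::pnorm(k - 0.5, spec$mean, spec$sd)
  p[1] <- stats::pnorm(0.5, spec$mean, spec$sd)  # pile sub-zero mass at 0
  keep <- p > 1e-10
  list(values = k[keep], probs = p[keep] / sum(p[keep]))
}

#' Parameters of a synthetic registry-like cohort
#'
#' @param n Number of casualties.
#' @param p1_prevalence True Priority One prevalence.
#' @param p1,not_p1 [class_physiology()] for each truth class.
#' @param missing_rates Named vector of per-field missingness
#'   probabilities (fields among `rr_bpm`, `hr_bpm`, `avpu`,
#'   `catastrophic_haemorrhage`, `breathing_after_airway_opened`,
#'   `can_walk`); defaults to none.
#' @param sentinel_code LSI code injected into true-P1 records so the
#'   ground-truth pathway ([is_priority_one()]) is exercised end-to-end
#'   rather than bypassed.
#' @param name Optional preset name.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n, p1_prevalence, p1, not_p1,
                          missing_rates = NULL,
                          sentinel_code = "intubation", name = "custom") {
  stopifnot(n > 0, p1_prevalence > 0, p1_prevalence < 1,
            inherits(p1, "class_physiology"),
            inherits(not_p1, "class_physiology"))
  mr <- c(rr_bpm = 0, hr_bpm = 0, avpu = 0, catastrophic_haemorrhage = 0,
          breathing_after_airway_opened = 0, can_walk = 0)
  if (!is.null(missing_rates)) {
    bad <- setdiff(names(missing_rates), names(mr))
    if (length(bad)) stop("unknown missing_rates field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    mr[names(missing_rates)] <- missing_rates
    stopifnot(all(mr >= 0 & mr <= 1))
  }
  structure(list(n = as.integer(n), p1_prevalence = p1_prevalence,
                 p1 = p1, not_p1 = not_p1, missing_rates = mr,
                 sentinel_code = sentinel_code, name = name),
            class = "cohort_params")
}

#' Load a packaged cohort preset
#'
#' Two presets emulate the coarse structure of the registry populations
#' triage tools are evaluated on: `"jttr-like"` (military registry
#' structure: P1 prevalence 47.6%) and `"tarn-like"` (civilian registry
#' structure: P1 prevalence 19.5%). Class-conditional physiology in the
#' preset files is *fitted* so the MPTT's analytic operating point lands
#' near the published registry values -- the presets are validation oracles
#' for the software, not reconstructions of registry data (see the preset
#' YAML comments and the methods vignette).
#'
#' @param preset `"jttr-like"`, `"tarn-like"`, or a path to a preset YAML.
#' @param n Cohort size (overrides the preset default).
#' @return A [cohort_params()] object.
#' @export
#' @examples
#' cohort_preset("jttr-like", n = 1000)
cohort_preset <- function(preset, n = NULL) {
  path <- if (file.exists(preset)) preset else {
    file <- paste0(gsub("-", "_", preset), ".yaml")
    p <- system.file("extdata", "presets", file, package = "mptt24")
    if (!nzchar(p)) stop("Unknown preset: ", preset, call. = FALSE)
    p
  }
  y <- yaml::read_yaml(path)
  as_phys <- function(b) class_physiology(
    rr = b$rr, hr = b$hr, alert_prob = b$alert_prob,
    cathaem_prob = b$cathaem_prob %||% 0, apnoea_prob = b$apnoea_prob %||% 0,
    walking_prob = b$walking_prob %||% 0
  )
  cohort_params(
    n = n %||% y$n %||% 10000L, p1_prevalence = y$p1_prevalence,
    p1 = as_phys(y$p1), not_p1 = as_phys(y$not_p1),
    missing_rates = unlist(y$missing_rates),
    sentinel_code = y$sentinel_code %||% "intubation",
    name = y$name %||% preset
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic casualty cohort with known ground truth
#'
#' Truth is drawn Bernoulli(`p1_prevalence`); physiology fields are drawn
#' independently from the truth class's distributions (a documented
#' simplification -- real registry physiology is correlated within
#' casualty). True-P1 records receive the sentinel LSI code, so the
#' LSI-based ground-truth computation is exercised rather than bypassed;
#' `truth` is also returned as a column for convenience.
#'
#' @param params A [cohort_params()] or preset name accepted by
#'   [cohort_preset()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param n Optional cohort-size override.
#' @return A [casualty_cohort()] tibble with an additional logical
#'   `truth` column.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_preset("jttr-like", n = 500), seed = 1)
#' mean(cohort$truth)
generate_cohort <- function(params, seed = NULL, n = NULL) {
  if (is.character(params)) params <- cohort_preset(params)
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(n)) params$n <- as.integer(n)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- params$n
  truth <- stats::runif(n) < params$p1_prevalence

  draw_class <- function(phys, m) {
    rr <- discrete_dist(phys$rr)
    hr <- discrete_dist(phys$hr)
    alert <- stats::runif(m) < phys$alert_prob
    avpu <- ifelse(alert, "A",
                   sample(c("V", "P", "U"), m, replace = TRUE,
                          prob = phys$vpu_probs))
    tibble::tibble(
      can_walk = stats::runif(m) < phys$walking_prob,
      catastrophic_haemorrhage = stats::runif(m) < phys$cathaem_prob,
      breathing_after_airway_opened = !(stats::runif(m) < phys$apnoea_prob),
      rr_bpm = sample(rr$values, m, replace = TRUE, prob = rr$probs),
      hr_bpm = sample(hr$values, m, replace = TRUE, prob = hr$probs),
      avpu = avpu
    )
  }

  out <- tibble::tibble(id = sprintf("s%06d", seq_len(n)), truth = truth)
  fields <- draw_class(params$not_p1, n)
  if (any(truth)) fields[truth, ] <- draw_class(params$p1, sum(truth))
  out <- dplyr::bind_cols(out, fields)

  for (field in names(params$missing_rates)) {
    rate <- params$missing_rates[[field]]
    if (rate > 0) {
      out[[field]][stats::runif(n) < rate] <- NA
    }
  }

  out$interventions <- ifelse(truth, params$sentinel_code, "")
  cohort <- casualty_cohort(out)
  cohort$truth <- out$truth
  cohort
}

#' Exact operating point of a tool on a parametrised population
#'
#' Enumerates the discrete joint distribution of the physiology fields
#' (independent given class) for each truth class, classifies every
#' support point with the actual decision-tree engine, and sums the
#' probability mass landing on P1. Returns the population sensitivity
#' (P(P1 call | true P1)) and specificity (1 - P(P1 call | true not-P1)) --
#' the values cohort-level estimates converge to as n grows. Missingness
#' rates are ignored (the operating point is defined on complete records).
#'
#' @param params A [cohort_params()] or preset name.
#' @param tool Tool identifier (see [triage_tools()]).
#' @param thresholds Optional threshold override list, as in
#'   [classify_cohort()].
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @export
#' @examples
#' analytic_operating_point(cohort_preset("jttr-like"), "mptt")
analytic_operating_point <- function(params, tool, thresholds = NULL) {
  if (is.character(params)) params <- cohort_preset(params)
  stopifnot(inherits(params, "cohort_params"))

  p_flag <- function(phys) {
    rr <- discrete_dist(phys$rr)
    hr <- discrete_dist(phys$hr)
    binary <- expand.grid(cathaem = c(TRUE, FALSE), walk = c(TRUE, FALSE),
                          apnoea = c(TRUE, FALSE), alert = c(TRUE, FALSE))
    bprob <- with(binary,
      ifelse(cathaem, phys$cathaem_prob, 1 - phys$cathaem_prob) *
      ifelse(walk, phys$walking_prob, 1 - phys$walking_prob) *
      ifelse(apnoea, phys$apnoea_prob, 1 - phys$apnoea_prob) *
      ifelse(alert, phys$alert_prob, 1 - phys$alert_prob))
    grid <- expand.grid(i_bin = seq_len(nrow(binary)),
                        i_rr = seq_along(rr$values),
                        i_hr = seq_along(hr$values))
    prob <- bprob[grid$i_bin] * rr$probs[grid$i_rr] * hr$probs[grid$i_hr]
    cohort <- casualty_cohort(tibble::tibble(
      can_walk = binary$walk[grid$i_bin],
      catastrophic_haemorrhage = binary$cathaem[grid$i_bin],
      breathing_after_airway_opened = !binary$apnoea[grid$i_bin],
      avpu = ifelse(binary$alert[grid$i_bin], "A", "V"),
      rr_bpm = rr$values[grid$i_rr],
      hr_bpm = hr$values[grid$i_hr]
    ))
    cat_out <- classify_cohort(cohort, tool, missing_policy = "exclude",
                               thresholds = thresholds)
    sum(prob[is_p1(cat_out)])
  }

  c(sensitivity = p_flag(params$p1),
    specificity = 1 - p_flag(params$not_p1))
}
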