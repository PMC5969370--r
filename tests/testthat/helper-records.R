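# One-row cohort builder with sensible non-triggering defaults: a breathing,
# non-ambulant, alert casualty with normal physiology and no interventions.
make_record <- function(can_walk = FALSE, breathing = TRUE, cathaem = FALSE,
                        rr = 16, hr = 80, avpu = "A", gcs = NA,
                        interventions = character()) {
  casualty_cohort(tibble::tibble(
    can_walk = can_walk,
    breathing_after_airway_opened = breathing,
    catastrophic_haemorrhage = cathaem,
    rr_bpm = rr, hr_bpm = hr, avpu = avpu, gcs_total = gcs,
    interventions = list(interventions)
  ))
}

# Fully observed random cohort for property-style tests.
random_cohort <- function(n, seed) {
  set.seed(seed)
  casualty_cohort(tibble::tibble(
    can_walk = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.2, .8)),
    breathing_after_airway_opened = sample(c(TRUE, FALSE), n, replace = TRUE,
                                           prob = c(.95, .05)),
    catastrophic_haemorrhage = sample(c(TRUE, FALSE), n, replace = TRUE,
                                      prob = c(.05, .95)),
    rr_bpm = sample(0:60, n, replace = TRUE),
    hr_bpm = sample(0:200, n, replace = TRUE),
    avpu = sample(c("A", "V", "P", "U"), n, replace = TRUE,
                  prob = c(.7, .15, .1, .05))
  ))
}

# Minimal two-class params for exact-oracle tests: point-mass distributions.
point_mass_params <- function(p1_rr, p1_hr, not_rr = 16, not_hr = 80,
                              p1_alert = 1, not_alert = 1,
                              p1_cathaem = 0, prevalence = 0.5) {
  cohort_params(
    n = 100, p1_prevalence = prevalence,
    p1 = class_physiology(rr = list(values = p1_rr,
                                    probs = rep(1 / length(p1_rr),
                                                length(p1_rr))),
                          hr = list(values = p1_hr,
                                    probs = rep(1 / length(p1_hr),
                                                length(p1_hr))),
                          alert_prob = p1_alert, cathaem_prob = p1_cathaem),
    not_p1 = class_physiology(rr = list(values = not_rr,
                                        probs = rep(1 / length(not_rr),
                                                    length(not_rr))),
                              hr = list(values = not_hr,
                                        probs = rep(1 / length(not_hr),
                                                    length(not_hr))),
                              alert_prob = not_alert)
  )
}
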