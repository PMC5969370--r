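# Threshold configuration for the primary triage tools. Thresholds are data,
# not code: classify_cohort() reads a block from this file (or a user copy)
# and runs the shared decision-tree engine, so variant tools are produced by
# editing thresholds, never by editing the classifier.
#
# Shared step order (short-circuiting at the first positive):
#   catastrophic haemorrhage (if used) -> walking -> breathing after airway
#   opened -> conscious level -> RR low -> RR high -> HR
#
# Boundary conventions:
#   rr_low     : P1 if RR <  rr_low   (all tools)
#   rr_high    : P1 if RR >= rr_high (MPTT family) or RR > rr_high (Sieve)
#   hr_high    : P1 if HR >= hr_high (MPTT family) or HR > hr_high (Sieve)

mptt:
  name: "MPTT"
  uses_catastrophic_haemorrhage: false
  conscious_rule: gcs_lt_14          # P1 if GCS total < 14
  rr_low: 12
  rr_high: 22
  rr_high_op: ">="
  hr_high: 100
  hr_high_op: ">="
  citation: >-
    Modified Physiological Triage Tool as derived by logistic regression on a
    military trauma cohort: GCS<14, RR<12 or RR>=22, HR>=100 flag P1.

mptt24:
  name: "MPTT-24"
  uses_catastrophic_haemorrhage: true
  conscious_rule: not_alert          # P1 if AVPU is not A (GCS>=14 bridge)
  rr_low: 12
  rr_high: 24
  rr_high_op: ">="
  hr_high: 100
  hr_high_op: ">="
  citation: >-
    MPTT variant with upper RR threshold raised to >=24 breaths/min (15-second
    count times four), conscious level on the AVPU scale, and a catastrophic
    external haemorrhage step ahead of the walking check.

uk_military_sieve:
  name: "UK Military Sieve"
  uses_catastrophic_haemorrhage: true
  conscious_rule: none
  rr_low: 10
  rr_high: 29
  rr_high_op: ">"                    # RR 10-29 inclusive passes
  hr_high: 120
  hr_high_op: ">"                    # pulse 121+ flags P1
  citation: >-
    UK military doctrine triage sieve: RR outside 10-29 breaths/min or pulse
    over 120 beats/min flags P1; capillary-refill alternative to the pulse
    check omitted (registry evaluations use heart rate). HR boundary resolved
    as strictly greater than 120 per the doctrinal "121 or more" wording.
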