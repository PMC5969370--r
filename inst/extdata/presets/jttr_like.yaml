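# JTTR-like synthetic cohort preset: emulates the coarse structure of a
# deployed military trauma-registry population (Priority One prevalence
# 47.6%). Class-conditional physiology below is FITTED (weighted least
# squares on the tools' closed-form flag rates) so that the MPTT's analytic
# operating point lands near the registry-published values (sensitivity
# ~69.9%, specificity ~65.3%), with the other tools' operating points as
# secondary targets. The registry publishes no physiology distributions, so
# these numbers are a validation oracle for the software, not registry
# estimates. RR/HR are discretised normals (integer breaths/min and
# beats/min, truncated at 0); fields are independent given class.
#
# Analytic operating points of this preset (sensitivity, specificity):
#   mptt   ~ (0.701, 0.632)    mptt24 ~ (0.687, 0.737)
#   sieve  ~ (0.407, 0.936)
name: jttr-like
n: 10000
p1_prevalence: 0.476
p1:
  rr: {mean: 20.6, sd: 9.0}
  hr: {mean: 82.0, sd: 30.0}
  alert_prob: 0.95
  cathaem_prob: 0.12
  apnoea_prob: 0.05
  walking_prob: 0.0
not_p1:
  rr: {mean: 18.5, sd: 5.1}
  hr: {mean: 72.0, sd: 9.0}
  alert_prob: 0.99
  cathaem_prob: 0.01
  apnoea_prob: 0.005
  walking_prob: 0.0
missing_rates: {}
sentinel_code: intubation
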