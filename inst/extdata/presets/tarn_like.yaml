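# TARN-like synthetic cohort preset: emulates the coarse structure of a
# civilian trauma-registry population (Priority One prevalence 19.5%).
# Class-conditional physiology is FITTED so the MPTT's analytic operating
# point lands near the registry-published values (sensitivity ~57.8%,
# specificity ~71.5%); see jttr_like.yaml for the fitting conventions and
# caveats.
#
# Analytic operating points of this preset (sensitivity, specificity):
#   mptt   ~ (0.586, 0.682)    mptt24 ~ (0.557, 0.780)
#   sieve  ~ (0.255, 0.948)
name: tarn-like
n: 10000
p1_prevalence: 0.195
p1:
  rr: {mean: 20.7, sd: 7.0}
  hr: {mean: 82.0, sd: 14.0}
  alert_prob: 0.95
  cathaem_prob: 0.12
  apnoea_prob: 0.05
  walking_prob: 0.0
not_p1:
  rr: {mean: 18.0, sd: 4.7}
  hr: {mean: 72.0, sd: 9.0}
  alert_prob: 0.99
  cathaem_prob: 0.01
  apnoea_prob: 0.005
  walking_prob: 0.0
missing_rates: {}
sentinel_code: intubation
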