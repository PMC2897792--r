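# Dominance scenario for rank-order checks.
# An AMI-like population in which mortality is driven in part by conditions
# that only the Elixhauser classification observes (arrhythmia, valvular
# disease, fluid/electrolyte disorders, coagulopathy, weight loss,
# deficiency anemia, depression, hypertension), and in which a share of the
# shared categories is coded with ICD-9-CM codes inside the Romano (but not
# the Deyo) code families. Point c-statistics on this scenario are expected
# to order Elixhauser > Charlson/Romano > Charlson/Deyo. The moderate
# carryover probability (0.5) with a higher prior-admission rate makes the
# one-year lookback informative for the Charlson variants.
n_patients: 5000
disease: AMI
age_mean: 66.31
age_sd: 13.36
male_frac: 0.72
aborigine_frac: 0.018
surgery_frac: 0.145
comorbidity_prevalences:
  chf: 0.22
  pvd: 0.10
  cvd: 0.12
  dementia: 0.08
  chronic_pulm: 0.12
  dm_uncomp: 0.15
  dm_comp: 0.06
  renal_failure: 0.08
  mild_liver: 0.03
  cancer: 0.04
  mets: 0.02
  arrhythmia: 0.18
  valvular: 0.10
  lytes: 0.15
  coag: 0.08
  wtloss: 0.10
  def_anemia: 0.12
  depression: 0.10
  htn: 0.35
  pud: 0.05
mortality_coefficients:
  age: 0.4
  male: 0.2
  aborigine: 0.15
  surgery: -0.3
  chf: 0.7
  pvd: 0.6
  cvd: 0.5
  dementia: 0.6
  chronic_pulm: 0.4
  dm_uncomp: 0.1
  dm_comp: 0.4
  renal_failure: 0.7
  mild_liver: 0.3
  cancer: 0.5
  mets: 1.2
  arrhythmia: 0.7
  valvular: 0.5
  lytes: 0.9
  coag: 0.9
  wtloss: 0.8
  def_anemia: 0.5
  depression: 0.4
  htn: 0.3
  pud: 0.2
mortality_intercepts:
  in_hospital: -3.342
  one_year: -2.300
prior_admission_rate: 1.2
carryover_prob: 0.5
seed: 1
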