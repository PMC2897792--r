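# AMI-like inpatient scenario.
# Demographic and mortality marginals follow the characteristics typical of
# an AMI claims cohort (mean age 66.31 +/- 13.36, 72% male, 14.94%
# in-hospital and 27.07% one-year mortality). Comorbidity prevalences and
# mortality coefficients are generator assumptions, not observed facts: no
# per-category prevalences are published for such cohorts, so plausible
# claims-study magnitudes are assumed. Intercepts are calibrated so the
# marginal mortality of the generated population hits the targets above.
n_patients: 5000
disease: AMI
age_mean: 66.31
age_sd: 13.36
male_frac: 0.7206
aborigine_frac: 0.018
surgery_frac: 0.145
comorbidity_prevalences:
  chf: 0.20
  pvd: 0.05
  cvd: 0.10
  dementia: 0.05
  chronic_pulm: 0.12
  dm_uncomp: 0.18
  dm_comp: 0.06
  renal_failure: 0.08
  mild_liver: 0.03
  cancer: 0.04
  mets: 0.015
  arrhythmia: 0.15
  valvular: 0.07
  lytes: 0.10
  coag: 0.03
  wtloss: 0.04
  def_anemia: 0.08
  depression: 0.05
  htn: 0.35
  pud: 0.04
mortality_coefficients:
  age: 0.45
  male: 0.2
  aborigine: 0.15
  surgery: -0.4
  chf: 0.5
  pvd: 0.3
  cvd: 0.4
  dementia: 0.4
  chronic_pulm: 0.25
  dm_uncomp: 0.1
  dm_comp: 0.35
  renal_failure: 0.6
  mild_liver: 0.3
  cancer: 0.5
  mets: 1.2
  arrhythmia: 0.3
  valvular: 0.15
  lytes: 0.6
  coag: 0.7
  wtloss: 0.6
  def_anemia: 0.2
  depression: 0.1
  htn: -0.1
  pud: 0.1
mortality_intercepts:
  in_hospital: -2.518
  one_year: -1.692
prior_admission_rate: 0.8
carryover_prob: 0.7
seed: 1
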