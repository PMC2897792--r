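# COPD-like inpatient scenario.
# Marginals follow the characteristics typical of a COPD claims cohort
# (mean age 72.54 +/- 12.10, 72% male, 4.12% aborigine, 1.17% surgery,
# 3.02% in-hospital and 22.48% one-year mortality). Prevalences and
# coefficients are generator assumptions (see ami.yaml); chronic pulmonary
# disease is the cohort condition and is therefore not a latent comorbidity
# here. Intercepts calibrated to the marginal mortality targets.
n_patients: 5000
disease: COPD
age_mean: 72.54
age_sd: 12.10
male_frac: 0.7220
aborigine_frac: 0.0412
surgery_frac: 0.0117
comorbidity_prevalences:
  chf: 0.15
  pvd: 0.04
  cvd: 0.12
  dementia: 0.08
  dm_uncomp: 0.15
  dm_comp: 0.05
  renal_failure: 0.05
  mild_liver: 0.03
  cancer: 0.06
  mets: 0.02
  arrhythmia: 0.10
  valvular: 0.04
  lytes: 0.08
  coag: 0.02
  wtloss: 0.08
  def_anemia: 0.08
  depression: 0.06
  htn: 0.35
  pud: 0.05
mortality_coefficients:
  age: 0.5
  male: 0.15
  aborigine: 0.2
  surgery: -0.2
  chf: 0.5
  pvd: 0.3
  cvd: 0.4
  dementia: 0.45
  dm_uncomp: 0.1
  dm_comp: 0.35
  renal_failure: 0.6
  mild_liver: 0.3
  cancer: 0.6
  mets: 1.3
  arrhythmia: 0.3
  valvular: 0.15
  lytes: 0.6
  coag: 0.7
  wtloss: 0.7
  def_anemia: 0.2
  depression: 0.1
  htn: -0.1
  pud: 0.1
mortality_intercepts:
  in_hospital: -4.333
  one_year: -1.954
prior_admission_rate: 0.8
carryover_prob: 0.7
seed: 1
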