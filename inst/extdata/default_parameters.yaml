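# Base-case inputs for the screening cost-utility model.
# Costs in 2024 Thai Baht; probabilities as proportions (a "%" suffix is
# also accepted, e.g. "75%"). Schema mirrors default_parameters().
prevalence:
  mg:
    value: 0.027        # AChR-Ab positive: 3/110
    cases: 3
    cohort: 110
  thyroid:
    value: 0.009        # abnormal TFT: 1/110
    cases: 1
    cohort: 110
accuracy:
  achr_ab:
    sensitivity: 0.75
    specificity: 0.98
  tft:                  # TSH-first reflex panel, composite accuracy
    sensitivity: 0.90
    specificity: 0.92
costs:
  achr_ab_test: 1900
  tsh: 170
  ft3: 170
  ft4: 150
  chest_ct: 8200
  mri_brain_orbit: 16000   # charged in every arm; cancels in increments
  followup_visit: 750
  visits_per_patient: 6    # two per year over the follow-up window
  followup_years: 3
  annual_treatment_mg: 0        # unpriced in the base case
  annual_treatment_thyroid: 0
utilities:
  idiopathic_ace: 1.0
  early_dx_omg: 0.872
  delayed_dx_omg: 0.739
  treated_hypothyroid: 0.94
  missed_condition: 0.965
  generalized_mg: 0.739    # defaults to the delayed-diagnosis value
  death: 0
transitions:               # annual probabilities; package defaults, all
  background_mortality: 0.005          # DSA/PSA-eligible and overridable
  omg_to_generalized: 0.05
  incident_omg: 0
  incident_hypothyroid: 0
  symptom_triggered_detection: 0.25
settings:
  discount_rate_annual: 0.03
  horizon_years: 10
  cohort_size: 110
  wtp_lower: 160000
  wtp_upper: 200000
  targeted_fraction: 0.30
  psa_draws: 10000
  dsa_variation: 0.20
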