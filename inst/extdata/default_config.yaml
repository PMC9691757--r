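# Reference clinic configuration: a 100-patient pediatric T1D practice with
# quarterly CDCES education visits. Any key may be overridden; omitted keys
# keep these defaults.
n_patients: 100
routine_visits_per_year: 4
routine_rate: 56.0            # USD per routine education visit
cdces_salary: 85000.0         # USD per year per full-time CDCES
sessions_per_day: 5
days_per_week: 5
weeks_per_year: 52            # 5 x 5 x 52 = 1,300 sessions/year
routine_minutes: 30.0
tele_minutes: 5.0
rpm_rate: 35.0                # USD per telemedicine contact (RPM CPT codes)
repurposed_visits_per_patient: 1
coverage_by_year: [0.75, 0.50]
periods_per_year: 12          # monthly review periods
hba1c_value_per_patient: 0.0  # USD/patient/year for a 0.5% HbA1c improvement
scenario: all
sensitivity:
  multipliers: [0.5, 1.5]
simulation:
  model: bernoulli
  flag_prob: 0.5
  seed: 1
output:
  dir: "."
  formats: [csv, md]
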