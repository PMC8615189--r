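name: atn_trial
infusion_duration: 0.5
horizon: 72
drugs:
  cefepime:
    mic: 8
    pct_time_threshold: 60
    vd_per_kg: {mean: 0.48, sd: 0.24, lower: 0.16, upper: 1.11, r2_weight: 0.4197, unit: L/kg}
    free_fraction: {mean: 0.79, sd: 0.09, lower: 0.72, upper: 0.85, unit: fraction}
    cl_nr: {mean: 24.33, sd: 11.25, lower: 13, upper: 44, r2_weight: 0.038, unit: mL/min}
    sieving: {mean: 0.67, sd: 0.13, lower: 0, upper: 1, unit: fraction}
  ceftazidime:
    mic: 8
    pct_time_threshold: 60
    vd_per_kg: {mean: 0.34, sd: 0.20, lower: 0.13, upper: 1.1, r2_weight: 0.0237, unit: L/kg}
    free_fraction: {mean: 0.86, sd: 0.05, lower: 0.75, upper: 0.94, unit: fraction}
    cl_nr: {mean: 15.9, sd: 9.9, lower: 8, upper: 37.7, r2_weight: 0.1254, unit: mL/min}
    sieving: {mean: 0.85, sd: 0.05, lower: 0, upper: 1, unit: fraction}
  ertapenem:
    mic: 1
    pct_time_threshold: 40
    vd_per_kg: {mean: 0.19, sd: 0.07, lower: 0.13, upper: 0.34, r2_weight: 0.3318, unit: L/kg}
    free_fraction: {mean: 0.25, sd: 0.45, lower: 0, upper: 1, unit: fraction}
    cl_nr: {mean: 11, sd: 3, lower: 10, upper: 19, r2_weight: 0.1156, unit: mL/min}
    sieving: {mean: 0.2, sd: 0.06, lower: 0, upper: 1, unit: fraction}
  imipenem:
    mic: 2
    pct_time_threshold: 40
    vd_per_kg: {mean: 0.34, sd: 0.1, lower: 0.21, upper: 0.63, r2_weight: 0.17, unit: L/kg}
    free_fraction: {mean: 0.8, sd: 0.16, lower: 0, upper: 1, unit: fraction}
    cl_nr: {mean: 100.5, sd: 28, lower: 53, upper: 160, r2_weight: 0.013, unit: mL/min}
    sieving: {mean: 0.57, sd: 0.1, lower: 0, upper: 1, unit: fraction}
  meropenem:
    mic: 2
    pct_time_threshold: 40
    vd_per_kg: {mean: 0.41, sd: 0.18, lower: 0.08, upper: 1.07, r2_weight: 0.1435, unit: L/kg}
    free_fraction: {mean: 0.79, sd: 0.09, lower: 0, upper: 1, unit: fraction}
    cl_nr: {mean: 54.9, sd: 49, lower: 0, upper: 251, r2_weight: 0.0072, unit: mL/min}
    sieving: {mean: 0.63, sd: 0.13, lower: 0, upper: 1, unit: fraction}
  piperacillin:
    mic: 16
    pct_time_threshold: 50
    vd_per_kg: {mean: 0.40, sd: 0.21, lower: 0, upper: 1.11, r2_weight: 0.0567, unit: L/kg}
    free_fraction: {mean: 0.76, sd: 0.2, lower: 0, upper: 1, unit: fraction}
    cl_nr: {mean: 48.5, sd: 37, lower: 0, upper: 187, r2_weight: 0.036, unit: mL/min}
    sieving: {mean: 0.6, sd: 0.28, lower: 0, upper: 1, unit: fraction}
  tazobactam:
    mic: 4
    pct_time_threshold: 50
    vd_per_kg: {mean: 0.50, sd: 0.37, lower: 0, upper: 2.13, r2_weight: 0.0049, unit: L/kg}
    free_fraction: {mean: 0.74, sd: 0.27, lower: 0, upper: 1, unit: fraction}
    cl_nr: {mean: 40.4, sd: 70, lower: 0, upper: 381, r2_weight: 0.0098, unit: mL/min}
    sieving: {mean: 0.8, sd: 0.36, lower: 0, upper: 1, unit: fraction}
arms:
  less_intensive:
    weight: {mean: 84.1, sd: 18.9, lower: 40, unit: kg}
    effluent_rate: {mean: 22, sd: 6.1, lower: 0, upper: 47.5, unit: mL/kg/h}
    delivered_fraction: {mean: 0.95, sd: 0.35, lower: 0, upper: 1, unit: fraction}
    replacement_rate: {mean: 0.83, sd: 0.25, lower: 0.33, upper: 1.33, unit: L/h}
  intensive:
    weight: {mean: 84.1, sd: 19.6, lower: 40, unit: kg}
    effluent_rate: {mean: 35.8, sd: 6.4, lower: 0, upper: 47.5, unit: mL/kg/h}
    delivered_fraction: {mean: 0.89, sd: 0.39, lower: 0, upper: 1, unit: fraction}
    replacement_rate: {mean: 0.89, sd: 0.39, lower: 0, upper: 1, unit: L/h}
regimens:
- {drug: cefepime, dose: 1000, interval: 12}
- {drug: cefepime, dose: 1000, interval: 8}
- {drug: cefepime, dose: 2000, interval: 12}
- {drug: cefepime, dose: 2000, interval: 8}
- {drug: ceftazidime, dose: 1000, interval: 12}
- {drug: ceftazidime, dose: 2000, interval: 12}
- {drug: piperacillin, dose: 3000, interval: 12}
- {drug: piperacillin, dose: 4000, interval: 12}
- {drug: piperacillin, dose: 3000, interval: 8}
- {drug: piperacillin, dose: 4000, interval: 8}
- {drug: piperacillin, dose: 3000, interval: 6}
- {drug: piperacillin, dose: 4000, interval: 6}
- {drug: tazobactam, dose: 375, interval: 12}
- {drug: tazobactam, dose: 500, interval: 12}
- {drug: tazobactam, dose: 375, interval: 8}
- {drug: tazobactam, dose: 375, interval: 6}
- {drug: tazobactam, dose: 500, interval: 8}
- {drug: tazobactam, dose: 500, interval: 6}
- {drug: ertapenem, dose: 1000, interval: 24, mic: 1, label: ertapenem 1000 mg q24h (MIC 1)}
- {drug: ertapenem, dose: 1000, interval: 24, mic: 2, label: ertapenem 1000 mg q24h (MIC 2)}
- {drug: imipenem, dose: 500, interval: 12}
- {drug: imipenem, dose: 500, interval: 8}
- {drug: imipenem, dose: 500, interval: 6}
- {drug: imipenem, dose: 1000, interval: 8}
- {drug: meropenem, dose: 500, interval: 12}
- {drug: meropenem, dose: 500, interval: 8}
- {drug: meropenem, dose: 1000, interval: 12}
- {drug: meropenem, dose: 1000, interval: 8}
- {drug: meropenem, dose: 2000, interval: 12}
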