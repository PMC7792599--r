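# SYNTHETIC default generation parameters for the 13 FTSTS condition classes.
# Invented, clinically plausible stand-ins bounded by the published cohort
# ranges (age (11,93] y, height [0.94,2.35) m, weight (22,120) kg); flagged
# non_canonical. Replace with harvested statistics where available.
test_type: FTSTS
non_canonical: true
source_note: >-
  Synthetic stand-in parameter set; not harvested from source publications.
classes:
  healthy:
    n: 240
    mu_time: 8.0
    sigma_time: 1.5
    mu_age: 42.0
    sigma_age: 14.0
    mu_bmi: 24.0
    sigma_bmi: 3.0
    mu_weight: 72.0
    sigma_weight: 12.0
    mu_height: 1.72
    sigma_height: 0.09
    pct_female: 0.50
  geriatric:
    n: 240
    mu_time: 13.0
    sigma_time: 3.0
    mu_age: 78.0
    sigma_age: 7.0
    mu_bmi: 26.0
    sigma_bmi: 4.0
    mu_weight: 69.0
    sigma_weight: 12.0
    mu_height: 1.64
    sigma_height: 0.09
    pct_female: 0.62
  geriatric_fallers:
    n: 240
    mu_time: 16.0
    sigma_time: 4.0
    mu_age: 80.0
    sigma_age: 7.0
    mu_bmi: 26.0
    sigma_bmi: 4.0
    mu_weight: 68.0
    sigma_weight: 12.0
    mu_height: 1.63
    sigma_height: 0.09
    pct_female: 0.64
  parkinsons_stage_1:
    n: 240
    mu_time: 11.0
    sigma_time: 2.5
    mu_age: 63.0
    sigma_age: 8.0
    mu_bmi: 26.0
    sigma_bmi: 3.5
    mu_weight: 74.0
    sigma_weight: 12.0
    mu_height: 1.68
    sigma_height: 0.09
    pct_female: 0.45
  parkinsons_stage_2:
    n: 240
    mu_time: 13.0
    sigma_time: 3.0
    mu_age: 66.0
    sigma_age: 8.0
    mu_bmi: 26.0
    sigma_bmi: 3.5
    mu_weight: 74.0
    sigma_weight: 12.0
    mu_height: 1.68
    sigma_height: 0.09
    pct_female: 0.45
  parkinsons_stage_2_5:
    n: 240
    mu_time: 14.5
    sigma_time: 3.5
    mu_age: 68.0
    sigma_age: 8.0
    mu_bmi: 26.5
    sigma_bmi: 3.5
    mu_weight: 75.0
    sigma_weight: 12.0
    mu_height: 1.67
    sigma_height: 0.09
    pct_female: 0.45
  parkinsons_stage_3:
    n: 240
    mu_time: 17.0
    sigma_time: 4.0
    mu_age: 70.0
    sigma_age: 8.0
    mu_bmi: 27.0
    sigma_bmi: 4.0
    mu_weight: 75.0
    sigma_weight: 13.0
    mu_height: 1.67
    sigma_height: 0.09
    pct_female: 0.45
  parkinsons_stage_4:
    n: 240
    mu_time: 21.0
    sigma_time: 5.0
    mu_age: 73.0
    sigma_age: 8.0
    mu_bmi: 27.0
    sigma_bmi: 4.0
    mu_weight: 74.0
    sigma_weight: 13.0
    mu_height: 1.66
    sigma_height: 0.09
    pct_female: 0.45
  parkinsons:
    n: 240
    mu_time: 14.0
    sigma_time: 4.0
    mu_age: 67.0
    sigma_age: 9.0
    mu_bmi: 26.0
    sigma_bmi: 3.5
    mu_weight: 74.0
    sigma_weight: 12.0
    mu_height: 1.68
    sigma_height: 0.09
    pct_female: 0.45
  arthritis:
    n: 240
    mu_time: 13.0
    sigma_time: 3.5
    mu_age: 63.0
    sigma_age: 10.0
    mu_bmi: 29.0
    sigma_bmi: 5.0
    mu_weight: 80.0
    sigma_weight: 15.0
    mu_height: 1.65
    sigma_height: 0.09
    pct_female: 0.60
  arthritis_knee_arthroplasty:
    n: 240
    mu_time: 15.0
    sigma_time: 4.0
    mu_age: 68.0
    sigma_age: 8.0
    mu_bmi: 30.0
    sigma_bmi: 5.0
    mu_weight: 83.0
    sigma_weight: 15.0
    mu_height: 1.65
    sigma_height: 0.09
    pct_female: 0.62
  stroke:
    n: 240
    mu_time: 18.0
    sigma_time: 5.0
    mu_age: 64.0
    sigma_age: 11.0
    mu_bmi: 27.0
    sigma_bmi: 4.0
    mu_weight: 76.0
    sigma_weight: 14.0
    mu_height: 1.68
    sigma_height: 0.09
    pct_female: 0.42
  vestibular_disorder:
    n: 240
    mu_time: 13.0
    sigma_time: 3.5
    mu_age: 56.0
    sigma_age: 12.0
    mu_bmi: 26.0
    sigma_bmi: 4.0
    mu_weight: 74.0
    sigma_weight: 13.0
    mu_height: 1.69
    sigma_height: 0.09
    pct_female: 0.52
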