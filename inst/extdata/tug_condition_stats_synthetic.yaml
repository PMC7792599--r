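# SYNTHETIC default generation parameters for the 18 TUG condition classes.
# The per-class summary statistics of the literature cohorts behind the TUG
# condition taxonomy are not published; the values below are invented,
# clinically plausible stand-ins bounded by the published cohort ranges
# (age [5,112] y, height [0.81,2.20) m, weight (30,136) kg) and are flagged
# non_canonical. Replace with harvested statistics where available.
test_type: TUG
non_canonical: true
source_note: >-
  Synthetic stand-in parameter set; not harvested from source publications.
classes:
  healthy:
    n: 280
    mu_time: 8.5
    sigma_time: 1.5
    mu_age: 45.0
    sigma_age: 15.0
    mu_bmi: 24.0
    sigma_bmi: 3.0
    mu_weight: 72.0
    sigma_weight: 12.0
    mu_height: 1.72
    sigma_height: 0.09
    pct_female: 0.50
  geriatric:
    n: 280
    mu_time: 12.5
    sigma_time: 3.0
    mu_age: 78.0
    sigma_age: 7.0
    mu_bmi: 26.0
    sigma_bmi: 4.0
    mu_weight: 70.0
    sigma_weight: 12.0
    mu_height: 1.65
    sigma_height: 0.09
    pct_female: 0.60
  parkinsons:
    n: 280
    mu_time: 14.0
    sigma_time: 4.0
    mu_age: 68.0
    sigma_age: 8.0
    mu_bmi: 26.0
    sigma_bmi: 3.5
    mu_weight: 75.0
    sigma_weight: 13.0
    mu_height: 1.68
    sigma_height: 0.09
    pct_female: 0.45
  parkinsons_nonfallers_medication:
    n: 280
    mu_time: 13.0
    sigma_time: 3.5
    mu_age: 67.0
    sigma_age: 8.0
    mu_bmi: 26.0
    sigma_bmi: 3.5
    mu_weight: 74.0
    sigma_weight: 12.0
    mu_height: 1.68
    sigma_height: 0.09
    pct_female: 0.45
  parkinsons_nonfallers_no_medication:
    n: 280
    mu_time: 13.5
    sigma_time: 3.5
    mu_age: 66.0
    sigma_age: 8.0
    mu_bmi: 26.0
    sigma_bmi: 3.5
    mu_weight: 74.0
    sigma_weight: 12.0
    mu_height: 1.68
    sigma_height: 0.09
    pct_female: 0.45
  parkinsons_fallers:
    n: 280
    mu_time: 17.0
    sigma_time: 5.0
    mu_age: 71.0
    sigma_age: 8.0
    mu_bmi: 27.0
    sigma_bmi: 4.0
    mu_weight: 76.0
    sigma_weight: 13.0
    mu_height: 1.67
    sigma_height: 0.09
    pct_female: 0.45
  dementia_mild_moderate:
    n: 280
    mu_time: 15.0
    sigma_time: 4.0
    mu_age: 80.0
    sigma_age: 6.0
    mu_bmi: 25.0
    sigma_bmi: 4.0
    mu_weight: 66.0
    sigma_weight: 11.0
    mu_height: 1.63
    sigma_height: 0.09
    pct_female: 0.65
  dementia_severe:
    n: 280
    mu_time: 22.0
    sigma_time: 6.0
    mu_age: 83.0
    sigma_age: 6.0
    mu_bmi: 24.0
    sigma_bmi: 4.0
    mu_weight: 62.0
    sigma_weight: 11.0
    mu_height: 1.61
    sigma_height: 0.09
    pct_female: 0.68
  arthritis_improvement:
    n: 280
    mu_time: 11.0
    sigma_time: 2.5
    mu_age: 66.0
    sigma_age: 9.0
    mu_bmi: 29.0
    sigma_bmi: 4.5
    mu_weight: 82.0
    sigma_weight: 14.0
    mu_height: 1.67
    sigma_height: 0.09
    pct_female: 0.60
  arthritis_knee_arthroplasty:
    n: 280
    mu_time: 13.0
    sigma_time: 3.0
    mu_age: 69.0
    sigma_age: 8.0
    mu_bmi: 30.0
    sigma_bmi: 5.0
    mu_weight: 84.0
    sigma_weight: 15.0
    mu_height: 1.66
    sigma_height: 0.09
    pct_female: 0.62
  arthritis:
    n: 280
    mu_time: 12.0
    sigma_time: 3.0
    mu_age: 64.0
    sigma_age: 10.0
    mu_bmi: 29.0
    sigma_bmi: 5.0
    mu_weight: 81.0
    sigma_weight: 15.0
    mu_height: 1.66
    sigma_height: 0.09
    pct_female: 0.60
  stroke:
    n: 280
    mu_time: 19.0
    sigma_time: 6.0
    mu_age: 65.0
    sigma_age: 11.0
    mu_bmi: 27.0
    sigma_bmi: 4.0
    mu_weight: 77.0
    sigma_weight: 14.0
    mu_height: 1.69
    sigma_height: 0.09
    pct_female: 0.42
  brain_injury:
    n: 280
    mu_time: 16.0
    sigma_time: 5.0
    mu_age: 42.0
    sigma_age: 13.0
    mu_bmi: 25.0
    sigma_bmi: 4.0
    mu_weight: 76.0
    sigma_weight: 14.0
    mu_height: 1.73
    sigma_height: 0.09
    pct_female: 0.35
  bilateral_vestibular_hypofunction:
    n: 280
    mu_time: 13.0
    sigma_time: 3.5
    mu_age: 58.0
    sigma_age: 12.0
    mu_bmi: 26.0
    sigma_bmi: 4.0
    mu_weight: 74.0
    sigma_weight: 13.0
    mu_height: 1.70
    sigma_height: 0.09
    pct_female: 0.50
  unilateral_vestibular_hypofunction:
    n: 280
    mu_time: 11.5
    sigma_time: 3.0
    mu_age: 55.0
    sigma_age: 12.0
    mu_bmi: 26.0
    sigma_bmi: 4.0
    mu_weight: 74.0
    sigma_weight: 13.0
    mu_height: 1.70
    sigma_height: 0.09
    pct_female: 0.52
  spinal_injury:
    n: 280
    mu_time: 20.0
    sigma_time: 7.0
    mu_age: 47.0
    sigma_age: 13.0
    mu_bmi: 25.0
    sigma_bmi: 4.0
    mu_weight: 74.0
    sigma_weight: 13.0
    mu_height: 1.74
    sigma_height: 0.09
    pct_female: 0.30
  paraplegia:
    n: 280
    mu_time: 26.0
    sigma_time: 8.0
    mu_age: 44.0
    sigma_age: 12.0
    mu_bmi: 24.0
    sigma_bmi: 4.0
    mu_weight: 72.0
    sigma_weight: 13.0
    mu_height: 1.74
    sigma_height: 0.09
    pct_female: 0.30
  tetraplegia:
    n: 280
    mu_time: 33.0
    sigma_time: 10.0
    mu_age: 43.0
    sigma_age: 12.0
    mu_bmi: 24.0
    sigma_bmi: 4.0
    mu_weight: 71.0
    sigma_weight: 13.0
    mu_height: 1.74
    sigma_height: 0.09
    pct_female: 0.28
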