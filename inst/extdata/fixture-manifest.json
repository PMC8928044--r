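{
  "expected_marginals": {
    "n_total": 200,
    "n_site_sf": 100,
    "n_site_pa": 100,
    "n_high": 158,
    "n_low": 42,
    "n_confirmed": 142,
    "n_probable": 16,
    "n_unlikely": 42,
    "table_granuloma_high": 142,
    "table_granuloma_low": 0,
    "table_nogranuloma_high": 16,
    "table_nogranuloma_low": 42,
    "icd9_first_high": 108,
    "icd10_first_high": 50,
    "icd9_first_confirmed": 98,
    "male_high": 142,
    "male_confirmed": 127,
    "african_american_high": 85,
    "african_american_confirmed": 74,
    "pulmonary_high": 143,
    "multi_organ_high": 60,
    "stage2_pulmonary": 47,
    "pft_available_pulmonary": 129,
    "scadding_stage0": 27,
    "scadding_stage1": 26,
    "scadding_stage2": 47,
    "scadding_stage3": 21,
    "scadding_stage4": 22,
    "scadding_missing": 15,
    "pft_obstructive": 28,
    "pft_restrictive": 36,
    "pft_mixed": 25,
    "pft_normal": 40,
    "pft_missing": 29,
    "group1": 60,
    "group2": 8,
    "group3": 45,
    "group4": 23,
    "group5": 17,
    "group6": 5,
    "group7": 0,
    "group8": 35,
    "group9": 6,
    "age_mean_confirmed": 65.5,
    "age_sd_confirmed": 10.8,
    "age_mean_probable": 69.3,
    "age_sd_probable": 10.3
  },
  "checksum": "088affd9cec5d755608a6e4c6a817e59",
  "cohort_file": "fixture_cohort.csv"
}
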