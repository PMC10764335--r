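# Default indicator schema: the 21 baseline laboratory / vital-sign indicators
# used for sepsis mortality-risk modelling ("max"/"min" = worst value over the
# ICU stay). survivor_mean / decedent_mean / sd parameterise the synthetic
# cohort generator; reference_value is the population normal used for
# imputation. All values are plausible placeholders in conventional clinical
# units, not estimates from any real cohort.
indicators:
  albumin_min:          {survivor_mean: 3.1,   decedent_mean: 2.5,   sd: 0.7,   reference_value: 4.0}
  alp_max:              {survivor_mean: 170.0, decedent_mean: 249.0, sd: 110.0, reference_value: 90.0}
  alt_max:              {survivor_mean: 120.0, decedent_mean: 220.0, sd: 160.0, reference_value: 30.0}
  ast_max:              {survivor_mean: 150.0, decedent_mean: 290.0, sd: 200.0, reference_value: 32.0}
  anion_gap_max:        {survivor_mean: 16.0,  decedent_mean: 19.0,  sd: 4.5,   reference_value: 12.0}
  bicarbonate_max:      {survivor_mean: 29.8,  decedent_mean: 27.0,  sd: 4.5,   reference_value: 24.0}
  blood_glucose_max:    {survivor_mean: 234.0, decedent_mean: 262.0, sd: 90.0,  reference_value: 100.0}
  bun_max:              {survivor_mean: 38.0,  decedent_mean: 48.0,  sd: 24.0,  reference_value: 14.0}
  inr_max:              {survivor_mean: 1.6,   decedent_mean: 2.1,   sd: 0.9,   reference_value: 1.0}
  lactate_max:          {survivor_mean: 2.7,   decedent_mean: 6.6,   sd: 2.4,   reference_value: 1.0}
  ph_max:               {survivor_mean: 7.435, decedent_mean: 7.431, sd: 0.06,  reference_value: 7.40}
  pt_max:               {survivor_mean: 17.0,  decedent_mean: 21.0,  sd: 7.0,   reference_value: 12.5}
  ptt_max:              {survivor_mean: 42.0,  decedent_mean: 52.0,  sd: 22.0,  reference_value: 30.0}
  serum_calcium_max:    {survivor_mean: 9.15,  decedent_mean: 9.20,  sd: 0.8,   reference_value: 9.4}
  serum_chloride_max:   {survivor_mean: 109.8, decedent_mean: 110.8, sd: 6.0,   reference_value: 102.0}
  serum_creatinine_max: {survivor_mean: 2.58,  decedent_mean: 3.62,  sd: 1.9,   reference_value: 0.9}
  serum_potassium_max:  {survivor_mean: 4.7,   decedent_mean: 4.9,   sd: 0.8,   reference_value: 4.2}
  serum_sodium_max:     {survivor_mean: 141.0, decedent_mean: 142.0, sd: 5.0,   reference_value: 140.0}
  total_bilirubin_max:  {survivor_mean: 1.9,   decedent_mean: 6.0,   sd: 4.0,   reference_value: 0.8}
  wbc_max:              {survivor_mean: 17.7,  decedent_mean: 24.4,  sd: 8.5,   reference_value: 8.0}
  age:                  {survivor_mean: 62.2,  decedent_mean: 66.9,  sd: 16.0,  reference_value: 60.0}
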