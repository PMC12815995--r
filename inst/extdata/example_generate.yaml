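# Minimal cohort-generation config: one preset arm plus one fully
# specified custom cohort.
seed: 1
cohorts:
  - preset: single_high
  - name: custom_controls
    n_animals: 5
    mean_vertebral_rate: 178
    sd_vertebral_rate: 21
    target_gm_mean: -11
    target_gm_sd: 17
    interval_days: 13
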