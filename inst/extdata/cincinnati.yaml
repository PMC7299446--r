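# Cincinnati CBSA (14 counties in OH/KY/IN), 2017 analysis configuration.
# Endpoint counts are person counts; the non-fatal ED count is already
# deduplicated for repeat visits (repeat_visit_fraction documents the 35%
# repeat-visit rate for users supplying raw ED event counts).
region_name: "Cincinnati CBSA"
population: 2165139
n_iter: 10000
seed: 1
averaging_scheme: comonotonic
repeat_visit_fraction: 0.35
models:
  - label: "Fatal Overdose"
    endpoint_count: 996
    multiplier_mean: 0.07182
    multiplier_se: 0.00533
    data_year: 2017
    adjust_repeat_visits: no
  - label: "Treatment Admissions"
    endpoint_count: 2752
    multiplier_mean: 0.21376
    multiplier_se: 0.02142
    data_year: 2016
    adjust_repeat_visits: no
  - label: "Non-Fatal ED Overdoses"
    endpoint_count: 7342
    multiplier_mean: 0.40890
    multiplier_se: 0.05111
    data_year: 2017
    adjust_repeat_visits: no
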