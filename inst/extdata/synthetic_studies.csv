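citation_tag,n_patients,proportion,se
synthetic_cohort_a,25000,0.0689,0.0016
synthetic_cohort_b,25000,0.0751,0.0017
synthetic_registry_c,26635,0.0715,0.0016
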