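Fully synthetic 12-patient fixture cohort, generated by
efindex::generate_cohort(sim_config(n_patients = 12, seed = 42)) and
written with write_cohort(). No real patient data. Regenerate with the
same call if the generator changes.
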