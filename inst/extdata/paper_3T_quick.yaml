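# Quick-scale baseline experiment at 3 T: 2 subjects x 200 realizations.
experiment: invivo
fields: [3T]
n_realizations: 200
n_subjects: 2
baseline: both
baseline_degree: 6
seed: 42
out_dir: p31corr_quick_out
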