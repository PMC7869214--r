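quantity	value
baseline_te_ratio	1.67
mrna_fold_control	1.6
protein_fold_control	2.4
mrna_fold_overexpressor	2.7
protein_fold_overexpressor	4.1
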