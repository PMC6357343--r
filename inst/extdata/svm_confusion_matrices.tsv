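dataset	tp	fp	fn	tn	precision_pct	accuracy_pct	sensitivity_pct	specificity_pct	auc
training	7	0	1	8	100	93.8	87.5	100	1
testing	7	0	1	8	100	93.8	87.5	100	0.984
rnaseq_testing	15	3	6	18	83.3	78.6	71.4	85.7	0.824
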