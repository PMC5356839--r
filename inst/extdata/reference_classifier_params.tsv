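model	delta	rho	mistakes	average_genes	n_genes
classifier_1	1	0.7	0	18	22
classifier_2	0.5	0.7	0	34	40
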