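module	n_same	n_total
linear_pathway	91	2417
covalent_modification	46	201
multiple_regulators	2	350
branch_point	5	2036
redundant_enzymes	0	114
physical_interaction	1378	3938
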