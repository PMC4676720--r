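ligand	metal	logK_ML	logK_MHL	pKas	dH_ML_kJmol	ref_ionic_strength	ref_temperature_C	source
EGTA	Ca	10.86	5.30	9.54;8.93;2.73;2.08	-33.4	0.1	20	NIST SMC 46 / Martell & Smith, 0.1 M KCl
EGTA	Mg	5.21	3.37	9.54;8.93;2.73;2.08	21.6	0.1	20	NIST SMC 46 / Martell & Smith, 0.1 M KCl
EGTA	Ba	8.30	4.40	9.54;8.93;2.73;2.08	-20.1	0.1	20	NIST SMC 46 / Martell & Smith, 0.1 M KCl
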