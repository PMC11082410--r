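rm	contribution_score	rate_of_contribution	h_plus	co2	per_unit	conditional
Purine dRN salvage synthesis	0.287	0.818	1	0	purine	FALSE
Proline synthesis	0.23	1	0	1	proline	FALSE
Tryptophan degradation	0.112	0.818	1	0	tryptophan	FALSE
Pyrimidine RN salvage synthesis	0.094	0.727	1	0	pyrimidine	FALSE
Pyrimidine dRN salvage synthesis	0.091	0.636	1	0	pyrimidine	TRUE
Phospholipid synthesis-PE	0.06	0.636	0	1	PE	FALSE
Phospholipid synthesis-PA	0.054	0.818	1	0	PA	FALSE
Phospholipid synthesis-PI	0.053	0.636	1	0	PI	FALSE
Phospholipid synthesis-PS	0.052	0.455	4	0	PS	FALSE
Phospholipid degradation	0.047	0.727	1	0	phospholipid	TRUE
Mevalonate pathway	0.041	0.545	0	1	farnesyl diphosphate	FALSE
Gluconeogenesis-specific	0.041	0.545	1	0	pyruvate	FALSE
Sialic acid synthesis	0.041	0.636	2	0	sialic acid	FALSE
Fatty acid transporter	0.033	0.909	1	0	fatty acid	FALSE
Beta-oxidation	0.032	0.455	1	0	fatty acid	FALSE
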