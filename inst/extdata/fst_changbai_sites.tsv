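population	JL-BS	JL-JL	JL-TH	JL-YB	HL	LN
JL-BS	NA	0.0118	0.0061	0.0088	0.1109	0.1523
JL-JL	0.0118	NA	-0.0031	0.0012	0.1111	0.1500
JL-TH	0.0061	-0.0031	NA	-0.0011	0.0857	0.1027
JL-YB	0.0088	0.0012	-0.0011	NA	0.0932	0.1448
HL	0.1109	0.1111	0.0857	0.0932	NA	0.2030
LN	0.1523	0.1500	0.1027	0.1448	0.2030	NA
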