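population	Changbai Mountain	North	Northwest	Qinghai-Tibet	South
Changbai Mountain	NA	0.2214	0.2129	0.2609	0.2225
North	0.2214	NA	0.0094	0.0534	0.0237
Northwest	0.2129	0.0094	NA	0.0557	0.0282
Qinghai-Tibet	0.2609	0.0534	0.0557	NA	0.0451
South	0.2225	0.0237	0.0282	0.0451	NA
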