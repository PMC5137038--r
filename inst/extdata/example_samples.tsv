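sample_id	chromosome	z	cv	prior
S01	21	13.7	0.40	1/4
S02	21	27.2	0.29	1/2
S03	21	12.4	0.31	1/79
S04	21	11.6	0.40	1/118
S05	21	14.4	0.33	1/141
S06	21	11.9	0.47	1/119
S07	21	19.7	0.32	1/13
S08	21	16.9	0.36	1/20
S09	21	26.2	0.29	1/115
S10	21	28.8	0.33	1/25
S11	21	4.9	0.33	1/43
S12	21	4.4	0.34	1/147
S13	21	4.2	0.32	1/80
S14	13	4.4	0.18	1:5000
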