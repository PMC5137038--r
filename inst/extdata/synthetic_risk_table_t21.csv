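age_years\weeks,10,12,14,16
20,0.00068,0.00064,0.00061,0.00058
25,0.00087,0.00082,0.00078,0.00074
30,0.0016,0.0015,0.0014,0.0013
35,0.0042,0.0039,0.0037,0.0035
40,0.016,0.015,0.014,0.013
45,0.055,0.052,0.049,0.046
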