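gene	scheme	phenotype	1e-07	1e-06	1e-05	1e-04
MAP4	v0	unadjusted	0	0	0.125	1
MAP4	v1	unadjusted	0.005	0.955	1	1
MAP4	v0	adjusted	0	0	0.12	1
MAP4	v1	adjusted	0.03	0.94	1	1
SCAP	v0	unadjusted	0	0	0	0
SCAP	v1	unadjusted	0	0.005	0.975	1
SCAP	v0	adjusted	0	0	0	0.015
SCAP	v1	adjusted	0	0.085	1	1
ARHGEF3	v0	unadjusted	0	0	0	0
ARHGEF3	v0	adjusted	0	0	0	0
ARHGEF3	v1	unadjusted	0	0	0	0
ARHGEF3	v1	adjusted	0	0	0	0
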