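category	singletons	duplicates	printed_ratio	printed_p
Total	305	114	2.68	NA
PCG	112	13	8.62	9.68e-05
TE	92	33	2.79	0.858
UI	125	71	1.76	0.023
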