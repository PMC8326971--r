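pos	A	C	G	T
1	0.35	0.35	0.18	0.12
2	0.60	0.15	0.12	0.13
3	0.10	0.04	0.80	0.06
4	0.02	0.02	0.94	0.02
5	0.02	0.02	0.02	0.94
6	0.60	0.04	0.32	0.04
7	0.70	0.08	0.10	0.12
8	0.06	0.04	0.84	0.06
9	0.16	0.16	0.20	0.48
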