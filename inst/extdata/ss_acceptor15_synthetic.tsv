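pos	A	C	G	T
1	0.15	0.30	0.15	0.40
2	0.15	0.30	0.15	0.40
3	0.15	0.30	0.15	0.40
4	0.15	0.30	0.15	0.40
5	0.15	0.30	0.15	0.40
6	0.15	0.30	0.15	0.40
7	0.15	0.30	0.15	0.40
8	0.15	0.30	0.15	0.40
9	0.15	0.30	0.15	0.40
10	0.15	0.30	0.15	0.40
11	0.25	0.30	0.15	0.30
12	0.20	0.40	0.05	0.35
13	0.94	0.02	0.02	0.02
14	0.02	0.02	0.94	0.02
15	0.25	0.10	0.50	0.15
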