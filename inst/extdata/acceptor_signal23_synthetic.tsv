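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
11	0.15	0.30	0.15	0.40
12	0.15	0.30	0.15	0.40
13	0.15	0.30	0.15	0.40
14	0.15	0.30	0.15	0.40
15	0.15	0.30	0.15	0.40
16	0.15	0.30	0.15	0.40
17	0.25	0.30	0.15	0.30
18	0.20	0.40	0.05	0.35
19	0.94	0.02	0.02	0.02
20	0.02	0.02	0.94	0.02
21	0.25	0.10	0.50	0.15
22	0.25	0.25	0.25	0.25
23	0.25	0.25	0.25	0.25
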