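pos	A	C	G	T
1	0.20	0.30	0.15	0.35
2	0.15	0.20	0.10	0.55
3	0.25	0.25	0.25	0.25
4	0.91	0.03	0.03	0.03
5	0.20	0.35	0.15	0.30
6	0.25	0.25	0.25	0.25
7	0.25	0.25	0.25	0.25
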