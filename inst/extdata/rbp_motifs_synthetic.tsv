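motif	protein
TTTT	SYN_PYR1
TTTTC	SYN_PYR2
CTCTCT	SYN_PYR3
TCCTCC	SYN_PYR4
GAAGAA	SYN_PUR1
AGGAGG	SYN_PUR2
TGCATG	SYN_FOX
ACTAAC	SYN_BP
GGGG	SYN_G4
ATTTA	SYN_ARE
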