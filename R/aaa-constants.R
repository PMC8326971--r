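# Shared constants (loaded first).
BASES <- c("A", "C", "G", "T")
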