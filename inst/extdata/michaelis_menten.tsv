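species	r1	r2	r3
# mass-action influence signs: +1 exactly at the reactant support
S0	+	0	0
E	+	0	0
ES0	0	+	+
S1	0	0	0
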