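species	r1	r2	r3	r4	r5	r6	r7	r8	r9	r10	r11	r12	r13
# mass-action influence signs: +1 exactly at the reactant support
E	+	0	0	0	0	0	0	0	0	0	0	0	0
S0	+	0	0	0	0	0	0	0	0	0	0	0	0
ES0	0	+	+	0	0	0	0	0	0	0	0	0	0
S1	0	0	0	+	0	0	+	0	0	0	0	0	0
F1	0	0	0	+	0	0	0	0	0	0	0	0	0
F1S1	0	0	0	0	+	+	0	0	0	0	0	0	0
P0	0	0	0	0	0	0	+	0	0	0	0	0	0
S1P0	0	0	0	0	0	0	0	+	+	0	0	0	0
P1	0	0	0	0	0	0	0	0	0	+	0	0	+
F2	0	0	0	0	0	0	0	0	0	+	0	0	0
F2P1	0	0	0	0	0	0	0	0	0	0	+	+	0
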