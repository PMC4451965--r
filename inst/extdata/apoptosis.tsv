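species	r1	r2	r3	r4	r5	r6	r7	r8	r9	r10	r11	r12	r13	r14
# mass-action influence signs: +1 exactly at the reactant support
C8s	+	0	0	0	0	0	0	0	0	0	0	+	0	0
C3	+	0	0	0	0	0	0	+	0	0	0	0	0	0
C3s	0	+	+	0	+	0	0	0	0	0	0	0	+	0
C8	0	+	0	0	0	+	0	0	0	0	0	0	0	0
IAP	0	0	+	0	+	0	0	0	0	+	0	0	0	0
Y	0	0	0	+	0	0	0	0	0	0	0	0	0	+
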