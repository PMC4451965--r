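species	r1	r2	r3	r4
# alternative kinetics: v3 depends on the reactant Xnuc only
Xcyt	+	0	0	0
Xnuc	0	+	+	0
Xnuc_p	0	0	0	+
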