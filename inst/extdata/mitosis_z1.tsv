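species	r1	r2	r3	r4
# phosphorylation rate v3 increases in both Xnuc (reactant) and Xnuc_p
# (product: self-activation via a Hill-type dependence on Xnuc + Xnuc_p)
Xcyt	+	0	0	0
Xnuc	0	+	+	0
Xnuc_p	0	0	+	+
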