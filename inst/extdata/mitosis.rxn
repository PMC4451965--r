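# Mitotic-trigger toy network: shuttling of the Cdk1-cyclin B1 complex X
# between cytoplasm (Xcyt) and nucleus (Xnuc), and its nuclear
# phosphorylation (Xnuc_p).
r1: Xcyt -> Xnuc
r2: Xnuc -> Xcyt
r3: Xnuc -> Xnuc_p
r4: Xnuc_p -> Xnuc
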