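# Basic caspase-activation model of apoptosis: caspase 8 (C8) and caspase 3
# (C3), active forms C8s/C3s, inhibitor of apoptosis protein IAP, complex
# Y = C3s:IAP; production and decay as inflow/outflow reactions
# (mass-action kinetics).
r1: C8s + C3 -> C8s + C3s
r2: C8 + C3s -> C8s + C3s
r3: C3s + IAP -> Y
r4: Y -> 0
r5: C3s + IAP -> C3s
r6: C8 -> 0
r7: 0 -> C8
r8: C3 -> 0
r9: 0 -> C3
r10: IAP -> 0
r11: 0 -> IAP
r12: C8s -> 0
r13: C3s -> 0
r14: Y -> C3s + IAP
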