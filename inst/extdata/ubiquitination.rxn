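# Ring1B/Bmi1 histone-H2A ubiquitination network (degradation omitted):
# 10 species, 15 reactions. B = Bmi1, R = Ring1B, Z = Bmi1-Ring1B complex,
# H = histone H2A; suffix _ub marks ubiquitinated forms, Bd_ub/Rd_ub the
# forms targeted for degradation, Ra_ub the self-ubiquitinated active form.
r1: B -> Bd_ub
r2: Bd_ub -> B
r3: R -> Rd_ub
r4: Rd_ub -> R
r5: B + R -> Z
r6: Z -> B + R
r7: Z -> Z_ub
r8: Z_ub -> Z
r9: Z_ub -> B + Ra_ub
r10: B + Ra_ub -> Z_ub
r11: R -> R_ub
r12: R_ub -> R
r13: Ra_ub -> R
r14: H -> H_ub
r15: H_ub -> H
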