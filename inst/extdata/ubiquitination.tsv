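species	r1	r2	r3	r4	r5	r6	r7	r8	r9	r10	r11	r12	r13	r14	r15
# Influence signs read off the published rate functions, one comment per
# non-obvious column (strict monotonicity of each printed rate):
#   v1 = k1*B              -> B+
#   v2 = k2*Bd_ub          -> Bd_ub+
#   v3 = k3*R              -> R+
#   v4 = k4*Rd_ub          -> Rd_ub+
#   v5 = k5*B*R            -> B+, R+
#   v6 = k6*Z              -> Z+
#   v7 = Z*(k7*Z + k8*Z_ub)        -> Z+, Z_ub+  (product Z_ub feeds back)
#   v8 = k9*Z_ub/(k10 + Z_ub)      -> Z_ub+      (Michaelis-Menten, increasing)
#   v9 = k11*Z_ub          -> Z_ub+
#   v10 = k12*B*Ra_ub      -> B+, Ra_ub+
#   v11 = k13*R^2 + k14*R*R_ub     -> R+, R_ub+  (product R_ub feeds back)
#   v12 = k14*R_ub         -> R_ub+
#   v13 = k15*Ra_ub        -> Ra_ub+
#   v14 = H*(k16*R_ub + k17*Z_ub + k18*Ra_ub) -> H+, R_ub+, Z_ub+, Ra_ub+
#   v15 = k19*H_ub         -> H_ub+
B	+	0	0	0	+	0	0	0	0	+	0	0	0	0	0
Bd_ub	0	+	0	0	0	0	0	0	0	0	0	0	0	0	0
R	0	0	+	0	+	0	0	0	0	0	+	0	0	0	0
Rd_ub	0	0	0	+	0	0	0	0	0	0	0	0	0	0	0
Z	0	0	0	0	0	+	+	0	0	0	0	0	0	0	0
Z_ub	0	0	0	0	0	0	+	+	+	0	0	0	0	+	0
Ra_ub	0	0	0	0	0	0	0	0	0	+	0	0	+	+	0
R_ub	0	0	0	0	0	0	0	0	0	0	+	+	0	+	0
H	0	0	0	0	0	0	0	0	0	0	0	0	0	+	0
H_ub	0	0	0	0	0	0	0	0	0	0	0	0	0	0	+
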