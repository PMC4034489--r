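# Parameter scaling factors selected by the single-perturbation screen:
# group "plus"  = factors whose scaling of the parameter gave a strong
#                 slow-down of tumour expansion at low glucose
#                 (relative change of the step count > 9 at 0.3 g/L);
# group "minus" = factors whose scaling gave a strong reduction of the final
#                 cell count at high glucose (relative change < -0.8 at
#                 4.5 g/L).
param	group	factor
k1	plus	10
k1	plus	50
k1	plus	100
k1	minus	0.01
k1_i	minus	0.01
k2	plus	10
k2	plus	50
k2	plus	100
k2	minus	0.01
k3	plus	0.01
k3	plus	0.1
k3	minus	50
k3	minus	100
k4	plus	0.01
k4	plus	0.1
k4	minus	50
k4	minus	100
k7	plus	0.01
k7	plus	0.1
k7	minus	50
k7	minus	100
k8	plus	10
k8	plus	50
k8	plus	100
k9	plus	0.01
k9	plus	0.1
k9	minus	50
k9	minus	100
k10	plus	10
k10	plus	50
k10	plus	100
k10	minus	0.01
k11_c1	minus	10
k11_c1	minus	50
k11_c1	minus	100
k11_m2	plus	50
k11_m2	plus	100
k11_c2	plus	0.01
k11_c2	plus	0.1
k11_c2	minus	5
k11_c2	minus	10
k11_c2	minus	50
k11_c2	minus	100
k12_i	minus	0.01
k12_i	minus	0.1
k12	plus	5
k12	plus	10
k12	plus	50
k12	plus	100
k12	minus	0.01
k12	minus	0.1
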