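# Baseline reaction constants of the intracellular miR-451/AMPK/mTORC1
# network, plus the glucose consumption rate r and the dimensionless
# consumption weights C1/C2 (not perturbed by the sensitivity sweep).
# DC = dimensionless constant.
name	value	unit	perturbable
k1	1.2e-9	pmol^-1 L s^-1	TRUE
k1_i	1	pmol L^-1	TRUE
k2	3e-2	pmol^-1 L s^-1	TRUE
k3	3e1	s^-1	TRUE
k4	1.4583e-2	s^-1	TRUE
k5	3.6e2	s^-1	TRUE
k6	1.0467e-2	s^-1	TRUE
k7	5.626e-3	s^-1	TRUE
k8	6.4167e-3	s^-1	TRUE
k9	6e-2	pmol^-1 L s^-1	TRUE
k10	3.6e2	s^-1	TRUE
k11_m1	5e2	pmol L^-1	TRUE
k11_c1	1.8e5	pmol L^-1 s^-1	TRUE
k11_m2	5e2	pmol L^-1	TRUE
k11_c2	1.8e6	pmol L s^-1	TRUE
k12_i	6e-1	DC	TRUE
k12	6e2	s^-1	TRUE
k13_m1	1e2	pmol L^-1	TRUE
k13_c1	6e2	pmol L^-1 s^-1	TRUE
k13_m2	1e2	pmol L^-1	TRUE
k13_c2	6e4	pmol L^-1 s^-1	TRUE
k14	3.6e2	s^-1	TRUE
k15_i	5	pmol L^-1	TRUE
k15	3.6e2	s^-1	TRUE
k16	3.6e2	s^-1	TRUE
k17_m1	1e2	pmol L^-1	TRUE
k17_c1	3.6e3	pmol L^-1 s^-1	TRUE
k17_m2	1e2	pmol L^-1	TRUE
k17_c2	3.6e5	pmol L^-1 s^-1	TRUE
k18_m	1.5104e3	pmol L^-1	TRUE
k18_c	4.86e3	pmol L^-1 s^-1	TRUE
r	1.17e-2	mmol L^-1 s^-1	FALSE
C1	8.571e-1	DC	FALSE
C2	1.429e-1	DC	FALSE
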