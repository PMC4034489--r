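# Molecular species of the intracellular network. x1-x9 are per-cell state
# variables of the ODE system; x10 is the extracellular glucose field held
# on the lattice.
variable	species	unit
x1	miR451	pmol L^-1
x2	MO25 mRNA	pmol L^-1
x3	MO25 miRNA bound	pmol L^-1
x4	MO25	pmol L^-1
x5	LKB1-STRAD	pmol L^-1
x6	AMPK phosphorylated	pmol L^-1
x7	TSC2 phosphorylated	pmol L^-1
x8	Rheb active	pmol L^-1
x9	mTOR C1 active	pmol L^-1
x10	Glucose	g L^-1
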