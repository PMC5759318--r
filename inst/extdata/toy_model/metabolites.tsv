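id	name	formula	charge	compartment
glc[e]	glc[e]		NA	e
glc[p]	glc[p]		NA	p
glc[c]	glc[c]		NA	c
pyr[c]	pyr[c]		NA	c
atp[c]	atp[c]		NA	c
adp[c]	adp[c]		NA	c
nad[c]	nad[c]		NA	c
nadh[c]	nadh[c]		NA	c
o2[e]	o2[e]		NA	e
o2[c]	o2[c]		NA	c
ect[c]	ect[c]		NA	c
co2[c]	co2[c]		NA	c
co2[e]	co2[e]		NA	e
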