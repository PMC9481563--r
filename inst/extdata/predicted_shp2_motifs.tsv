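protein	category	sequence	matched_consensus	effectors	confirmed
AFAP1L2	Cytoskeletal	esdrvYLDLTPvksfl	Y[ILV].[ILV][ST]P; Y.[DE].[ST]P	PLCg; SRC	0
TNS1	Cytoskeletal	asdgqYENQSPeatsp	Y.N.[ST]P	GRB2	0
TRIOBP	Cytoskeletal	rqaldYVELSPltqas	Y[ILV].[ILV][ST]P; Y.[DE].[ST]P	PLCg; SRC	0
BCR	RhoGEFs/GAPs	qdglpYIDDSPsssph	Y.[DE].[ST]P	SRC	0
PYK2	Misc pTyr signaling	ldpmvYMNDKSPltpek	Y.N..[ST]P	GRB2	0
CD28	Receptor/adaptor	llhsdYMNMTPrrpgp	Y..M[ST]P; Y.N.[ST]P	PI3K; GRB2	1
GAB1	Receptor/adaptor	iqeanYVPMTPgtfdf	Y..M[ST]P	PI3K	0
GAB2	Receptor/adaptor	nsqsvYIPMSPgahhf	Y..M[ST]P	PI3K	0
IRS1	Receptor/adaptor	htddgYMPMSPgvapv	Y..M[ST]P	PI3K	1
IRS1	Receptor/adaptor	kgsgdYMPMSPksvsa	Y..M[ST]P	PI3K	1
IRS1	Receptor/adaptor	vdpngYMMMSPsggcs	Y..M[ST]P	PI3K	0
IRS1	Receptor/adaptor	pctgdYMNMSPvgdsn	Y..M[ST]P	PI3K	0
IRS2	Receptor/adaptor	lpngdYLNVSPsdavt	Y.N.[ST]P; Y[ILV].[ILV][ST]P	GRB2; PLCg	0
IRS2	Receptor/adaptor	gaddgYMPMTPgaala	Y..M[ST]P	PI3K	0
IRS2	Receptor/adaptor	crsddYMPMSPasvsa	Y..M[ST]P	PI3K	0
IRS2	Receptor/adaptor	gdsdqYVLMSSPvgril	Y..M.[ST]P	PI3K	0
HNRNPK	mRNA binding	psrrdYDDMSPrrgpp	Y..M[ST]P; Y.[DE].[ST]P	PI3K; SRC	0
LARP1	mRNA binding	pespnYRNTRTPrtprt	Y.N..[ST]P	GRB2	0
DPF2	Gene regulation	lddedYEEDTPkrrgk	Y.[DE].[ST]P	SRC	0
KMT5A	Gene regulation	gqskiYSYMSPnkcsg	Y..M[ST]P	PI3K	0
ZC3H4	Gene regulation	kghrkYREYSPpyaps	Y.[DE].[ST]P	SRC	0
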