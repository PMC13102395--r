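kind	residue	atom
donor	ARG	NE
donor	ARG	NH1
donor	ARG	NH2
donor	LYS	NZ
donor	HIS	ND1
donor	HIS	NE2
donor	ASN	ND2
donor	GLN	NE2
donor	SER	OG
donor	THR	OG1
donor	TYR	OH
donor	TRP	NE1
donor	backbone	N
acceptor	DNA	O1P
acceptor	DNA	O2P
acceptor	DNA	O3'
acceptor	DNA	O5'
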