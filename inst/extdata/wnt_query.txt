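# Wnt signaling pathway query network: 11 proteins, 17 interactions.
# Reconstructed from the canonical pathway: ligand-receptor binding
# (WNT1, FZD1, A2MR), Dishevelled activation and inhibition of the
# degradation complex, the GSK3B/AXIN1/APC/CTNNB1 complex, beta-catenin/
# TCF7 displacing TLE1, and induction of MYC. Edge-list format; the
# individual edges are a reconstruction, the 11/17 counts are the facts.
WNT1	FZD1
WNT1	A2MR
FZD1	A2MR
FZD1	DVL1
DVL1	GSK3B
DVL1	AXIN1
DVL1	APC
GSK3B	AXIN1
GSK3B	APC
GSK3B	CTNNB1
AXIN1	APC
AXIN1	CTNNB1
APC	CTNNB1
CTNNB1	TCF7
TCF7	TLE1
TCF7	MYC
CTNNB1	MYC
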