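# Default structural-alert SMARTS (reactive / assay-interfering groups).
# Format: ID<TAB>SMARTS. The curation engine accepts any pattern list.
acyl_halide	[CX3](=O)[F,Cl,Br,I]
sulfonyl_halide	[SX4](=O)(=O)[F,Cl,Br,I]
anhydride	[CX3](=O)O[CX3](=O)
peroxide	[OX2][OX2]
azide	[NX2]=[NX2+]=[NX1-]
diazo	[CX3]=[NX2+]=[NX1-]
isocyanate	[NX2]=C=[OX1]
isothiocyanate	[NX2]=C=[SX1]
thiocyanate	[SX2]C#N
aldehyde	[CX3H1](=O)[#6]
epoxide	C1OC1
aziridine	C1NC1
nitroso	[NX2]=[OX1]
nitro_aliphatic	[CX4][NX3+](=O)[O-]
disulfide	[SX2][SX2]
phosphorus	[P]
michael_acceptor	[CX3]=[CX3][CX3](=O)[OX2,NX3,#6]
alkyl_halide_activated	[CX4][Br,I]
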