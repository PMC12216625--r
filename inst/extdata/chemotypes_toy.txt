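# Toy chemotype library for tests/examples: core substructures of the
# fixture scaffolds. Format: ID<TAB>pattern (SMILES substructure).
quinazoline	c1ccc2ncncc2c1
benzothiazole	c1ccc2scnc2c1
benzimidazole	c1ccc2[nH]cnc2c1
phenyl_triazine	c1ccc(-c2ncncn2)cc1
anilide	O=CNc1ccccc1
phenylpiperazine	c1ccc(N2CCNCC2)cc1
quinoline	c1ccc2ncccc2c1
phenylfuran	c1ccc(-c2occc2)cc1
phenylthiazole	c1ccc(-c2nccs2)cc1
diaryl_ether	c1ccc(Oc2ccccc2)cc1
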