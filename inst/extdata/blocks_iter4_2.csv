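id,smiles,role,iteration
as01,NC1CCNCC1,amine_scaffold,4.2
as02,NCC1CCNCC1,amine_scaffold,4.2
as03,NC1CCNC1,amine_scaffold,4.2
as04,NC1CCCNCC1,amine_scaffold,4.2
ic01,O=C=NC,isocyanate,4.2
ic02,O=C=NCC,isocyanate,4.2
aa01,NCC(=O)O,amino_acid,4.2
aa02,CC(N)C(=O)O,amino_acid,4.2
aa03,NCCC(=O)O,amino_acid,4.2
aa04,NC(c1ccccc1)C(=O)O,amino_acid,4.2
sc01,CS(=O)(=O)Cl,sulfonyl_chloride,4.2
sc02,CCS(=O)(=O)Cl,sulfonyl_chloride,4.2
sc03,CCCS(=O)(=O)Cl,sulfonyl_chloride,4.2
sc04,CCCCS(=O)(=O)Cl,sulfonyl_chloride,4.2
sc05,CCCCCS(=O)(=O)Cl,sulfonyl_chloride,4.2
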