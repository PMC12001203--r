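id,smiles,role,iteration
pz,C1CNCCN1,scaffold,3.0
ac01,CC(=O)O,acid,3.0
ac02,CCC(=O)O,acid,3.0
ac03,CCCC(=O)O,acid,3.0
ac04,CCCCC(=O)O,acid,3.0
ac05,CCCCCC(=O)O,acid,3.0
ac06,CCCCCCC(=O)O,acid,3.0
ac07,CCCCCCCC(=O)O,acid,3.0
ac08,CCCCCCCCC(=O)O,acid,3.0
ac09,CCCCCCCCCC(=O)O,acid,3.0
ac10,CCCCCCCCCCC(=O)O,acid,3.0
ac11,CC(C)C(=O)O,acid,3.0
ac12,CC(C)CC(=O)O,acid,3.0
ac13,CCC(C)C(=O)O,acid,3.0
ac14,CC(C)(C)CC(=O)O,acid,3.0
ac15,C1CC1C(=O)O,acid,3.0
ac16,C1CCC1C(=O)O,acid,3.0
sc01,CS(=O)(=O)Cl,sulfonyl_chloride,3.0
sc02,CCS(=O)(=O)Cl,sulfonyl_chloride,3.0
sc03,CCCS(=O)(=O)Cl,sulfonyl_chloride,3.0
sc04,CCCCS(=O)(=O)Cl,sulfonyl_chloride,3.0
sc05,CCCCCS(=O)(=O)Cl,sulfonyl_chloride,3.0
sc06,CCCCCCS(=O)(=O)Cl,sulfonyl_chloride,3.0
sc07,CCCCCCCS(=O)(=O)Cl,sulfonyl_chloride,3.0
sc08,CCCCCCCCS(=O)(=O)Cl,sulfonyl_chloride,3.0
sc09,CCCCCCCCCS(=O)(=O)Cl,sulfonyl_chloride,3.0
sc10,CCCCCCCCCCS(=O)(=O)Cl,sulfonyl_chloride,3.0
sc11,CC(C)S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc12,CC(C)CS(=O)(=O)Cl,sulfonyl_chloride,3.0
sc13,CCC(C)S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc14,CC(C)(C)CS(=O)(=O)Cl,sulfonyl_chloride,3.0
sc15,C1CC1S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc16,C1CCC1S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc17,C1CCCC1S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc18,C1CCCCC1S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc19,C1CCCCCC1S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc20,c1ccccc1S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc21,Cc1ccccc1S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc22,CCc1ccccc1S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc23,Cc1cccn1CS(=O)(=O)Cl,sulfonyl_chloride,3.0
sc24,c1ccc(F)cc1S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc25,c1cccc(F)c1S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc26,c1ccc(Cl)cc1S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc27,c1cccc(Cl)c1S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc28,c1ccc(Br)cc1S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc29,c1cccc(Br)c1S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc30,c1ccc(C)cc1S(=O)(=O)Cl,sulfonyl_chloride,3.0
sc31,c1ccccc1CS(=O)(=O)Cl,sulfonyl_chloride,3.0
sc32,c1ccc(OC)cc1S(=O)(=O)Cl,sulfonyl_chloride,3.0
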