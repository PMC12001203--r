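id,smiles,role,iteration
mpz,C[C@H]1CNCCN1,scaffold,3.5
ac01,CC(=O)O,acid,3.5
ac02,CCC(=O)O,acid,3.5
ac03,CCCC(=O)O,acid,3.5
ac04,CCCCC(=O)O,acid,3.5
ac05,CCCCCC(=O)O,acid,3.5
ac06,CCCCCCC(=O)O,acid,3.5
ac07,CCCCCCCC(=O)O,acid,3.5
ac08,CCCCCCCCC(=O)O,acid,3.5
ac09,CCCCCCCCCC(=O)O,acid,3.5
ac10,CCCCCCCCCCC(=O)O,acid,3.5
ac11,CC(C)C(=O)O,acid,3.5
ac12,CC(C)CC(=O)O,acid,3.5
ac13,CCC(C)C(=O)O,acid,3.5
ac14,CC(C)(C)CC(=O)O,acid,3.5
ac15,C1CC1C(=O)O,acid,3.5
ac16,C1CCC1C(=O)O,acid,3.5
ac17,C1CCCC1C(=O)O,acid,3.5
ac18,C1CCCCC1C(=O)O,acid,3.5
ac19,C1CCCCCC1C(=O)O,acid,3.5
ac20,c1ccccc1C(=O)O,acid,3.5
ac21,Cc1ccccc1C(=O)O,acid,3.5
ac22,CCc1ccccc1C(=O)O,acid,3.5
ac23,Cc1cccn1CC(=O)O,acid,3.5
ac24,c1ccc(F)cc1C(=O)O,acid,3.5
ac25,c1cccc(F)c1C(=O)O,acid,3.5
ac26,c1ccc(Cl)cc1C(=O)O,acid,3.5
ac27,c1cccc(Cl)c1C(=O)O,acid,3.5
ac28,c1ccc(Br)cc1C(=O)O,acid,3.5
ac29,c1cccc(Br)c1C(=O)O,acid,3.5
ac30,c1ccc(C)cc1C(=O)O,acid,3.5
ac31,c1ccccc1CC(=O)O,acid,3.5
ac32,c1ccc(OC)cc1C(=O)O,acid,3.5
sc01,CS(=O)(=O)Cl,sulfonyl_chloride,3.5
sc02,CCS(=O)(=O)Cl,sulfonyl_chloride,3.5
sc03,CCCS(=O)(=O)Cl,sulfonyl_chloride,3.5
sc04,CCCCS(=O)(=O)Cl,sulfonyl_chloride,3.5
sc05,CCCCCS(=O)(=O)Cl,sulfonyl_chloride,3.5
sc06,CCCCCCS(=O)(=O)Cl,sulfonyl_chloride,3.5
sc07,CCCCCCCS(=O)(=O)Cl,sulfonyl_chloride,3.5
sc08,CCCCCCCCS(=O)(=O)Cl,sulfonyl_chloride,3.5
sc09,CCCCCCCCCS(=O)(=O)Cl,sulfonyl_chloride,3.5
sc10,CCCCCCCCCCS(=O)(=O)Cl,sulfonyl_chloride,3.5
sc11,CC(C)S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc12,CC(C)CS(=O)(=O)Cl,sulfonyl_chloride,3.5
sc13,CCC(C)S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc14,CC(C)(C)CS(=O)(=O)Cl,sulfonyl_chloride,3.5
sc15,C1CC1S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc16,C1CCC1S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc17,C1CCCC1S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc18,C1CCCCC1S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc19,C1CCCCCC1S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc20,c1ccccc1S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc21,Cc1ccccc1S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc22,CCc1ccccc1S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc23,Cc1cccn1CS(=O)(=O)Cl,sulfonyl_chloride,3.5
sc24,c1ccc(F)cc1S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc25,c1cccc(F)c1S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc26,c1ccc(Cl)cc1S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc27,c1cccc(Cl)c1S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc28,c1ccc(Br)cc1S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc29,c1cccc(Br)c1S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc30,c1ccc(C)cc1S(=O)(=O)Cl,sulfonyl_chloride,3.5
sc31,c1ccccc1CS(=O)(=O)Cl,sulfonyl_chloride,3.5
sc32,c1ccc(OC)cc1S(=O)(=O)Cl,sulfonyl_chloride,3.5
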