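id,smiles,role,iteration
pz,C1CNCCN1,scaffold,2.0
ac01,CC(=O)O,acid,2.0
ac02,CCC(=O)O,acid,2.0
ac03,CCCC(=O)O,acid,2.0
ac04,CCCCC(=O)O,acid,2.0
ac05,CCCCCC(=O)O,acid,2.0
ac06,CCCCCCC(=O)O,acid,2.0
ac07,CCCCCCCC(=O)O,acid,2.0
ac08,CCCCCCCCC(=O)O,acid,2.0
ac09,CCCCCCCCCC(=O)O,acid,2.0
ac10,CCCCCCCCCCC(=O)O,acid,2.0
ac11,CC(C)C(=O)O,acid,2.0
ac12,CC(C)CC(=O)O,acid,2.0
ac13,CCC(C)C(=O)O,acid,2.0
ac14,CC(C)(C)CC(=O)O,acid,2.0
ac15,C1CC1C(=O)O,acid,2.0
ac16,C1CCC1C(=O)O,acid,2.0
ac17,C1CCCC1C(=O)O,acid,2.0
ac18,C1CCCCC1C(=O)O,acid,2.0
ac19,C1CCCCCC1C(=O)O,acid,2.0
ac20,c1ccccc1C(=O)O,acid,2.0
ac21,Cc1ccccc1C(=O)O,acid,2.0
ac22,CCc1ccccc1C(=O)O,acid,2.0
ac23,Cc1cccn1CC(=O)O,acid,2.0
ac24,c1ccc(F)cc1C(=O)O,acid,2.0
ac25,c1cccc(F)c1C(=O)O,acid,2.0
ac26,c1ccc(Cl)cc1C(=O)O,acid,2.0
ac27,c1cccc(Cl)c1C(=O)O,acid,2.0
ac28,c1ccc(Br)cc1C(=O)O,acid,2.0
ac29,c1cccc(Br)c1C(=O)O,acid,2.0
ac30,c1ccc(C)cc1C(=O)O,acid,2.0
ac31,c1ccccc1CC(=O)O,acid,2.0
ac32,c1ccc(OC)cc1C(=O)O,acid,2.0
ac33,c1cccc(OC)c1C(=O)O,acid,2.0
ac34,c1ccccc1OCC(=O)O,acid,2.0
ac35,c1ccc(C(F)(F)F)cc1C(=O)O,acid,2.0
ac36,c1cccc(C(F)(F)F)c1C(=O)O,acid,2.0
ac37,c1ccc(N(C)C)cc1C(=O)O,acid,2.0
ac38,c1cccc(N(C)C)c1C(=O)O,acid,2.0
ac39,c1ccccc1N(C)CC(=O)O,acid,2.0
ac40,c1ccc(CC)cc1C(=O)O,acid,2.0
ac41,c1ccccc1CCC(=O)O,acid,2.0
ac42,CCOCC(=O)O,acid,2.0
ac43,CCCOCC(=O)O,acid,2.0
ac44,CCOCCC(=O)O,acid,2.0
ac45,CCCCOCC(=O)O,acid,2.0
ac46,C1CCOCC1C(=O)O,acid,2.0
ac47,C1CCOC1C(=O)O,acid,2.0
ac48,CC1CCCC1C(=O)O,acid,2.0
ac49,CC1CCCCC1C(=O)O,acid,2.0
ac50,C1CC2CCC1CC2C(=O)O,acid,2.0
ac51,c1ccc2ccccc2c1C(=O)O,acid,2.0
ac52,Cc1ccc2ccccc2c1C(=O)O,acid,2.0
ac53,CCCCCCCCCCCC(=O)O,acid,2.0
ac54,CCCCCCCCCCCCC(=O)O,acid,2.0
ac55,CCCCCCCCCCCCCC(=O)O,acid,2.0
ac56,CCCCCCCCCCCCCCC(=O)O,acid,2.0
ac57,CCCCCCCCCCCCCCCC(=O)O,acid,2.0
ac58,CCCCCCCCCCCCCCCCC(=O)O,acid,2.0
ac59,CCCCCCCCCCCCCCCCCC(=O)O,acid,2.0
ac60,CCCCCCCCCCCCCCCCCCC(=O)O,acid,2.0
ac61,CCCCCCCCCCCCCCCCCCCC(=O)O,acid,2.0
ac62,CCCCCCCCCCCCCCCCCCCCC(=O)O,acid,2.0
ac63,CCCCCCCCCCCCCCCCCCCCCC(=O)O,acid,2.0
ac64,CCCCCCCCCCCCCCCCCCCCCCC(=O)O,acid,2.0
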