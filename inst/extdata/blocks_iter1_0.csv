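id,smiles,role,iteration
scaf1,O=C(c1ccco1)N1CCNCC1,scaffold,1.0
ncO01,O=C=NC,isocyanate,1.0
ncO02,O=C=NCC,isocyanate,1.0
ncO03,O=C=NCCC,isocyanate,1.0
ncO04,O=C=NCCCC,isocyanate,1.0
ncO05,O=C=NCCCCC,isocyanate,1.0
ncO06,O=C=NCCCCCC,isocyanate,1.0
ncO07,O=C=NCCCCCCC,isocyanate,1.0
ncO08,O=C=NCCCCCCCC,isocyanate,1.0
ncO09,O=C=NCCCCCCCCC,isocyanate,1.0
ncO10,O=C=NCCCCCCCCCC,isocyanate,1.0
ncO11,O=C=NCC(C)C,isocyanate,1.0
ncO12,O=C=NCC(C)(C)C,isocyanate,1.0
ncO13,O=C=NC1CC1,isocyanate,1.0
ncO14,O=C=NC1CCC1,isocyanate,1.0
ncO15,O=C=NC1CCCC1,isocyanate,1.0
ncO16,O=C=NC1CCCCC1,isocyanate,1.0
ncO17,O=C=NC1CCCCCC1,isocyanate,1.0
ncO18,O=C=Nc1ccccc1,isocyanate,1.0
ncO19,O=C=NCc1ccccc1,isocyanate,1.0
ncO20,O=C=NCCc1ccccc1,isocyanate,1.0
ncO21,O=C=NCc1ccco1,isocyanate,1.0
ncO22,O=C=NCc1cccs1,isocyanate,1.0
ncO23,O=C=NCc1cccn1C,isocyanate,1.0
ncO24,O=C=Nc1ccc(F)cc1,isocyanate,1.0
ncO25,O=C=Nc1cccc(F)c1,isocyanate,1.0
ncO26,O=C=Nc1ccccc1F,isocyanate,1.0
ncO27,O=C=Nc1ccc(Cl)cc1,isocyanate,1.0
ncO28,O=C=Nc1cccc(Cl)c1,isocyanate,1.0
ncO29,O=C=Nc1ccccc1Cl,isocyanate,1.0
ncO30,O=C=Nc1ccc(Br)cc1,isocyanate,1.0
ncO31,O=C=Nc1cccc(Br)c1,isocyanate,1.0
ncO32,O=C=Nc1ccccc1Br,isocyanate,1.0
ncO33,O=C=Nc1ccc(C)cc1,isocyanate,1.0
ncO34,O=C=Nc1cccc(C)c1,isocyanate,1.0
ncO35,O=C=Nc1ccccc1C,isocyanate,1.0
ncO36,O=C=Nc1ccc(OC)cc1,isocyanate,1.0
ncO37,O=C=Nc1cccc(OC)c1,isocyanate,1.0
ncO38,O=C=Nc1ccccc1OC,isocyanate,1.0
ncO39,O=C=Nc1ccc(C(F)(F)F)cc1,isocyanate,1.0
ncO40,O=C=Nc1cccc(C(F)(F)F)c1,isocyanate,1.0
ncO41,O=C=Nc1ccccc1C(F)(F)F,isocyanate,1.0
ncO42,O=C=Nc1ccc(N(C)C)cc1,isocyanate,1.0
ncO43,O=C=Nc1cccc(N(C)C)c1,isocyanate,1.0
ncO44,O=C=Nc1ccccc1N(C)C,isocyanate,1.0
ncO45,O=C=Nc1ccc(CC)cc1,isocyanate,1.0
ncO46,O=C=Nc1cccc(CC)c1,isocyanate,1.0
ncO47,O=C=Nc1ccccc1CC,isocyanate,1.0
ncO48,O=C=NCCOC,isocyanate,1.0
ncO49,O=C=NCCCOC,isocyanate,1.0
ncO50,O=C=NCCOCC,isocyanate,1.0
ncO51,O=C=NCCCCOC,isocyanate,1.0
ncO52,O=C=NC1CCOCC1,isocyanate,1.0
ncO53,O=C=NC1CCOC1,isocyanate,1.0
ncO54,O=C=NCC1CCCC1,isocyanate,1.0
ncO55,O=C=NCC1CCCCC1,isocyanate,1.0
ncO56,O=C=NC1CC2CCC1CC2,isocyanate,1.0
ncO57,O=C=Nc1ccc2ccccc2c1,isocyanate,1.0
ncO58,O=C=NCc1ccc2ccccc2c1,isocyanate,1.0
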