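id: iter4.2
description: two parallel branches merged by a final amide coupling
adducts: ["[M+H]+"]
steps:
  - id: ureaA
    rxn: '[NX3;H2,H1;!$(N[C,S]=O):1].[NX2:2]=[CX2:3]=[OX1:4]>>[N:1][C:3](=[O:4])[N:2]'
    roles: [amine_scaffold, isocyanate]
    leaving: ""
  - id: sulfB
    rxn: '[NX3;H2,H1;!$(N[C,S]=O):1].[SX4:2](=[OX1:3])(=[OX1:4])[Cl]>>[N:1][S:2](=[O:3])=[O:4]'
    roles: [amino_acid, sulfonyl_chloride]
    leaving: HCl
  - id: merge
    rxn: '[NX3;H2,H1;!$(N[C,S]=O):1].[CX3:2](=[OX1:3])[OX2H1]>>[N:1][C:2]=[O:3]'
    roles: ["@ureaA", "@sulfB"]
    leaving: H2O
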