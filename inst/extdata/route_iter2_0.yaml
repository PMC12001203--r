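id: iter2.0
description: amide vector from piperazine, one step
adducts: ["[M+H]+"]
steps:
  - id: amide1
    rxn: '[NX3;H2,H1;!$(N[C,S]=O):1].[CX3:2](=[OX1:3])[OX2H1]>>[N:1][C:2]=[O:3]'
    roles: [scaffold, acid]
    leaving: H2O
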