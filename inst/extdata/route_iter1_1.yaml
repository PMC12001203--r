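id: iter1.1
description: urea vector from the acetyl-piperazine core (no furan), one step
adducts: ["[M+H]+"]
steps:
  - id: urea1
    rxn: '[NX3;H2,H1;!$(N[C,S]=O):1].[NX2:2]=[CX2:3]=[OX1:4]>>[N:1][C:3](=[O:4])[N:2]'
    roles: [scaffold, isocyanate]
    leaving: ""
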