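gene_a,gene_b
GENE1,GENE2
GENE1,GENE3
GENE2,GENE3
GENE3,GENE4
GENE2,GENE4
GENE2,GENE5
GENE4,GENE5
GENE4,GENE6
GENE2,GENE6
GENE4,GENE7
GENE1,GENE7
GENE4,GENE8
GENE5,GENE8
GENE4,GENE9
GENE6,GENE9
GENE9,GENE10
GENE2,GENE10
GENE4,GENE11
GENE10,GENE11
GENE11,GENE12
GENE2,GENE12
GENE5,GENE13
GENE6,GENE13
GENE12,GENE14
GENE2,GENE14
GENE14,GENE15
GENE12,GENE15
GENE2,GENE16
GENE8,GENE16
GENE5,GENE17
GENE14,GENE17
GENE6,GENE18
GENE14,GENE18
DUP1,GENE1
DUP1,GENE2
NOVO1,GENE1
DUP2,GENE3
DUP2,GENE1
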