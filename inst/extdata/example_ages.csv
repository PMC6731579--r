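gene,branch,mechanism
GENE1,0,ancestral
GENE2,0,ancestral
GENE3,0,ancestral
GENE4,0,ancestral
GENE5,0,ancestral
GENE6,0,ancestral
GENE7,0,ancestral
GENE8,0,ancestral
GENE9,0,ancestral
GENE10,0,ancestral
GENE11,0,ancestral
GENE12,0,ancestral
GENE13,0,ancestral
GENE14,0,ancestral
GENE15,0,ancestral
GENE16,0,ancestral
GENE17,0,ancestral
GENE18,0,ancestral
DUP1,1,Dl
NOVO1,4,A
DUP2,9,R
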