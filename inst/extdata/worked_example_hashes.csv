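fun,kmer,value,synthetic
1,GGCAA,57,FALSE
1,GCAAT,27,FALSE
1,CAATT,24,FALSE
2,CAATT,36,FALSE
1,AATTG,52,FALSE
1,ATTGT,36,FALSE
2,ATTGT,27,FALSE
1,TTGTG,22,FALSE
1,TGTGT,34,FALSE
2,TGTGT,30,FALSE
1,GTGTG,49,FALSE
2,GTGTG,47,FALSE
1,GTGTC,38,FALSE
2,GTGTC,25,FALSE
1,TGTCG,56,FALSE
2,TGTCG,41,TRUE
2,GGCAA,118,TRUE
2,GCAAT,119,TRUE
2,AATTG,120,TRUE
2,TTGTG,121,TRUE
1,AAAAA,60,TRUE
2,AAAAA,61,TRUE
1,AGCAA,100,TRUE
2,AGCAA,101,TRUE
1,CGCAA,102,TRUE
2,CGCAA,103,TRUE
1,TGCAA,104,TRUE
2,TGCAA,105,TRUE
1,AGGCA,106,TRUE
2,AGGCA,107,TRUE
1,CGGCA,108,TRUE
2,CGGCA,109,TRUE
1,GGGCA,110,TRUE
2,GGGCA,111,TRUE
1,TGGCA,112,TRUE
2,TGGCA,113,TRUE
1,ATGTG,114,TRUE
2,ATGTG,115,TRUE
1,CTGTG,116,TRUE
2,CTGTG,117,TRUE
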