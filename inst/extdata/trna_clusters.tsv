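cluster	upstream_gene	downstream_gene	trnas
1	atp8	nad4L	trnW,trnD
2	nad5	rnl	trnR,trnC,trnN
3	cox2	nad2	trnA,trnF,trnY,trnM,trnL,trnG,trnM,trnE,trnT,trnI,trnK
4	nad3	nad1	trnS,trnQ,trnH
5	rns	atp6	trnV,trnL,trnR
6	atp6	rps3	trnS,trnP
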