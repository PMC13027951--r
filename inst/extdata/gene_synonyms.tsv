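synonym	canonical
cox1	cox1
coi	cox1
co1	cox1
coxi	cox1
cytochrome c oxidase subunit 1	cox1
cytochrome c oxidase subunit i	cox1
cytochrome oxidase subunit 1	cox1
mt-co1	cox1
cox2	cox2
coii	cox2
co2	cox2
coxii	cox2
cytochrome c oxidase subunit 2	cox2
cytochrome c oxidase subunit ii	cox2
cox3	cox3
coiii	cox3
co3	cox3
coxiii	cox3
cytochrome c oxidase subunit 3	cox3
cytochrome c oxidase subunit iii	cox3
cob	cob
cytb	cob
cyt b	cob
cob1	cob
apocytochrome b	cob
cytochrome b	cob
nad1	nad1
nd1	nad1
nadh1	nad1
nadh dehydrogenase subunit 1	nad1
nad2	nad2
nd2	nad2
nadh2	nad2
nadh dehydrogenase subunit 2	nad2
nad3	nad3
nd3	nad3
nadh3	nad3
nadh dehydrogenase subunit 3	nad3
nad4	nad4
nd4	nad4
nadh4	nad4
nadh dehydrogenase subunit 4	nad4
nad4l	nad4L
nd4l	nad4L
nadh dehydrogenase subunit 4l	nad4L
nad5	nad5
nd5	nad5
nadh5	nad5
nadh dehydrogenase subunit 5	nad5
nad6	nad6
nd6	nad6
nadh6	nad6
nadh dehydrogenase subunit 6	nad6
atp6	atp6
atpase6	atp6
atpase 6	atp6
atp synthase f0 subunit 6	atp6
atp8	atp8
atpase8	atp8
atpase 8	atp8
atp synthase f0 subunit 8	atp8
atp9	atp9
atpase9	atp9
atpase 9	atp9
atp synthase f0 subunit 9	atp9
rps3	rps3
rps-3	rps3
ribosomal protein s3	rps3
rnl	rnl
rrnl	rnl
l-rrna	rnl
lsu	rnl
large subunit ribosomal rna	rnl
l rrna	rnl
rrn26	rnl
rns	rns
rrns	rns
s-rrna	rns
ssu	rns
small subunit ribosomal rna	rns
s rrna	rns
rrn18	rns
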