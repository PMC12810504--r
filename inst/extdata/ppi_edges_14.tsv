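source	target
PARP1	KDR
SLC6A4	PIK3CA
OPRM1	SLC6A2
OPRM1	KDR
MAOB	SLC6A4
OPRM1	OPRD1
GSK3B	EGFR
MAOA	PIK3CA
GSK3B	MAOB
OPRM1	EGFR
OPRD1	ADORA1
SLC6A3	PNOC
GSK3B	PARP1
MAOA	SLC6A4
EGFR	OPRD1
EGFR	PARP1
GSK3B	PIK3CA
SLC6A3	SLC6A2
EGFR	MAOB
MAOA	SLC6A3
GSK3B	MAOA
OPRD1	SLC6A2
OPRM1	MAOB
OPRM1	PIK3CA
MAOA	MAOB
GSK3B	SLC6A3
OPRM1	SLC6A4
SLC6A3	ADORA1
KDR	PNOC
MAOA	PARP1
EGFR	SLC6A4
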