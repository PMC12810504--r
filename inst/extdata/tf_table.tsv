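NFKB	EGFR	Unknown	curated
NFKB	ADORA1	Unknown	curated
NFKB	GSK3B	Unknown	curated
NFKB	OPRM1	Unknown	curated
SP1	EGFR	Unknown	curated
SP1	OPRM1	Unknown	curated
SP1	MAOB	Unknown	curated
SP1	KDR	Unknown	curated
YY1	EGFR	Unknown	curated
YY1	OPRM1	Unknown	curated
YY1	PARP1	Unknown	curated
SP3	MAOB	Unknown	curated
SP3	OPRM1	Unknown	curated
SP3	KDR	Unknown	curated
SP4	MAOB	Unknown	curated
SP4	KDR	Unknown	curated
YBX1	EGFR	Unknown	curated
YBX1	SLC6A4	Unknown	curated
ESR1	KDR	Unknown	curated
ESR1	EGFR	Unknown	curated
STAT1	OPRM1	Unknown	curated
STAT1	EGFR	Unknown	curated
STAT3	EGFR	Unknown	curated
STAT3	OPRM1	Unknown	curated
JUN	EGFR	Unknown	curated
JUN	OPRM1	Unknown	curated
RELA	ADORA1	Unknown	curated
RELA	EGFR	Unknown	curated
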