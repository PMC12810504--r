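gene	name	degree	betweenness	closeness
OPRM1	opioid receptor mu 1	7	0.342	0.684
GSK3B	glycogen synthase kinase 3 beta	6	0.208	0.590
EGFR	epidermal growth factor receptor	6	0.286	0.649
MAOA	monoamine oxidase A	6	0.090	0.619
SLC6A3	solute carrier family 6 member 3	5	0.022	0.520
MAOB	monoamine oxidase B	5	0.070	0.565
SLC6A4	solute carrier family 6 member 4	5	0.022	0.520
PIK3CA	phosphatidylinositol-4,5-bisphosphate 3-kinase catalytic subunit alpha	4	0.011	0.481
PARP1	poly(ADP-ribose) polymerase 1	4	0.011	0.481
OPRD1	opioid receptor delta 1	4	0.017	0.481
KDR	kinase insert domain receptor	3	0	0.433
SLC6A2	solute carrier family 6 member 2	3	0.005	0.481
ADORA1	adenosine A1 receptor	2	0	0.448
PNOC	prepronociceptin	2	0	0.433
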