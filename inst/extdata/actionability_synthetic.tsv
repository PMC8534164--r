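gene	alteration	drug	tumor_type	evidence_level
PIK3CA	snv	alpelisib	BRCA	level_1
AKT1	snv	capivasertib	BRCA	level_1
EGFR	snv	erlotinib	NSCLC	level_1
EGFR	amplification	erlotinib	NSCLC	level_2
KRAS	snv	sotorasib	NSCLC	level_1
BRCA1	deletion	olaparib	OV	level_2
PTEN	deletion	capivasertib	ST	level_3
CCND1	amplification	palbociclib	BRCA	level_3
CDK6	amplification	palbociclib	ST	level_3
MCL1	amplification	tapotoclax	ST	level_4
TSC2	snv	everolimus	ST	level_2
ESR1	snv	fulvestrant	BRCA	level_2
MDM4	amplification	idasanutlin	ST	level_4
FGFR3	amplification	erdafitinib	BC	level_2
JAK2	amplification	ruxolitinib	ST	level_4
TP53	snv	eprenetapopt	ST	level_4
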