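TP53	tsg
EP300	tsg
MCL1	oncogene
IGF1R	oncogene
RB1	tsg
NOTCH3	oncogene
AKT2	oncogene
CCNE1	oncogene
CDKN1B	tsg
CCND1	oncogene
MDM4	oncogene
MYC	oncogene
AKT3	oncogene
CDK6	oncogene
JAK2	oncogene
KRAS	oncogene
BAP1	tsg
ARID1A	tsg
BRCA1	tsg
PTEN	tsg
CDKN2A	tsg
CDKN2B	tsg
PBRM1	tsg
TERT	oncogene
AKT1	oncogene
EGFR	oncogene
FGFR3	oncogene
PIK3CA	oncogene
JAK3	oncogene
TSC2	tsg
ESR1	oncogene
CDH1	tsg
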