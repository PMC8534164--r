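gene	pathway
TP53	transcription factors
ESR1	transcription factors
MYC	transcription factors
NOTCH3	transcription factors
MDM4	transcription factors
EP300	chromatin
ARID1A	chromatin
PBRM1	chromatin
BAP1	chromatin
RB1	cell cycle
CCND1	cell cycle
CCNE1	cell cycle
CDK6	cell cycle
CDKN1B	cell cycle
CDKN2A	cell cycle
CDKN2B	cell cycle
PIK3CA	PIK3/mTOR
PTEN	PIK3/mTOR
AKT1	PIK3/mTOR
AKT2	PIK3/mTOR
AKT3	PIK3/mTOR
TSC2	PIK3/mTOR
IGF1R	PIK3/mTOR
KRAS	RAS/MAPK
EGFR	RAS/MAPK
FGFR3	RAS/MAPK
JAK2	JAK-STAT
JAK3	JAK-STAT
BRCA1	DNA repair
CDH1	cell adhesion
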