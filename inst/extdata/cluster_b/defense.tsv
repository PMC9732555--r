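symptom	ATS	BDL	NAR	HST	PAG	norm	norm_low	pd	pd_group
MD-Acting-out	85.7	84.3		70.0		27.9		60.0	PD-MD
MD-Idealization		67.1				27.1		44.3	PD-MD
MD-Denial	75.7	78.6	80.0	77.1		38.6		28.6	PD-MD
MD-Dissociation	47.1		55.0	72.1		15.0		55.0	PD-MD
MD-Devaluation		85.0	44.3			17.9		69.3	PD-MD
MD-Projection	76.4		70.0			42.1		34.3	PD-MD
MD-Projective-identification					77.9	21.4		62.9	PD-MD
MD-Splitting		87.9		72.1		22.9		64.3	PD-MD
MD-Displacement					70.0	24.3		54.3	PD-MD
MD-Passive-aggression		71.4		58.6	88.6	24.3		48.6	PD-MD
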