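protein	partner	relation
ACT1	PFN1	binding/association
ACT1	CAPZ	complex
ACT1	ROCK1	activation
ACT1	COF1	dissociation
TPM1	TNNC1	complex
TPM1	ACT1	binding/association
TPM1	MYH9	binding/association
TNNC1	TNNI1	complex
TNNC1	CA2	activation
LMNA	EMD	binding/association
LMNA	CDK1	phosphorylation
LMNA	PP1	dephosphorylation
VIM	PLEC	binding/association
VIM	CDC2	phosphorylation
TUBB	STMN1	inhibition
TUBB	MAP4	binding/association
TUBB	KIF5B	complex
STMN1	CAMK2	phosphorylation
MREB	FTSZ	indirect effect
KIF5B	RAB3	activation
ROCK1	LIMK1	activation
LIMK1	COF1	inhibition
COF1	ACT1	state change
MYH9	RLC	phosphorylation
CAPZ	TWF1	indirect effect
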