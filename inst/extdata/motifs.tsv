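name	iupac
FOXH1	AATCCACA
SBE	AGAC
POU5F1	ATGCAAAT
TEAD	GGAATG
NANOG	TAATGG
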