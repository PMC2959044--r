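name	start_column	pattern
NKL	41	[AKST][DENPS][LAST]QV
HOXL	46	[KT][IV]WFQNRR[AMV]K[DEHKLMQWY][KR][KR]
HOXL2	16	LE[AGKNR]E
PRD	16	L[EINQRV][^DGHMPTVWY][^CDGKMNPQR][FL][^CFILPTWY][AEFHKQRV][ADEGKNSTW][CHKMPQR][FHY]P
SINE_ETSY	3	ETSY
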