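name	domain	signature	intron_codons	accession
TALE
MlPbx	Pbx	insert(NLA) 23	2,47/48	HM444125
MlMeis	MeisA, MeisD	insert(HLT) 23	25/26, 51	HM444091
MlPknox	Pbx	insert(HLG) 23	25/26, 51	HM444122
POU
MlPou1	Pou			HM444110
MlPOU26a	Pou			HM444092
MlPOU26b				HM444093
MlPOU26c				HM444094
LIM
MlIsl	Lim		39	HM444123
MlLhx1.5	Lim		55/56	HM444088
MlLhx3.4	Lim		27	HM444089
MlLmx	Lim		11,55/56	HM444090
SIX
MlSIX13a	Six			HM444111
MlSIX13b	Six			HM444112
MlSIX13c	Six			HM444113
MlSIX13d	Six		12,58	HM444114
MlSIX13e	Six			HM444115
MlSIX13f	Six			HM444130
MlSIX27	Six		17	HM444128
MlSIX28	Six			HM444129
MlSIX32a				HM444116
MlSIX32b	Six			HM444144
MlSIX32c	Six		30	HM444117
MlSIX36	Six	NKL	45	HM444118
MlSIX41	Six		9,45	HM444127
MlSIX59a	Six		57*	HM444131
MlSIX59b	Six		57*	HM444119
MlSIX59c	Six		57*	HM444120
MlSIX59d	Six		57*	HM444121
MlSIX59e	Six		57*	HM444126
ANTP
MlANTP03a		HOXL2		HM444145
MlANTP03b		HOXL2		HM444132
MlANTP03c				HM444134
MlANTP03d				HM444072
MlANTP19		NKL	21/22	HM444073
MlANTP21			10,52	HM444074
MlANTP22			13/14	HM444075
MlANTP23			18	HM444140
MlANTP25				HM444076
MlANTP35			44/45	HM444077
MlANTP37		NKL, HOXL	44-45	HM444078
MlANTP47			46-47	HM444079
MlANTP48		NKL, HOXL2	21-22	HM444080
MlANTP51			36	HM444136
MlANTP63			12/13	HM444137
MlANTP65			12/13,45	HM444081*
MlANTP66			46/47	HM444082*
MlANTP67			17/18,47	HM444083*
MlANTP68		NKL	14/15,44/45	HM444084*
MlANTP71		NKL	9,53	HM444085
MlANTP72		NKL	44/45	HM444086
MlANTP78			39	HM444087
PRD
MlPRD10a		PRD	37	HM444097
MlPRD10b		PRD	24,46/47	HM444098*
MlPRD16	Octapeptide	PRD	46/47	HM444102*
MlPRD43	Octapeptide		46/47	HM444104
MlPRD44		PRD, HOXL2	46/47	HM444105*
MlPRD50	Octapeptide		14/15,46/47	HM444141
MlPRD61	Octapeptide	PRD	12/13,46/47	HM444147
Unclassified
MlHD01				HM444143
MlHD05				HM444146
MlHD07a				HM444139
MlHD07b				HM444095
MlHD07c				HM444096
MlHD11a				HM444133
MlHD11b				HM444099
MlHD14				HM444100
MlHD15				HM444101
MlHD31				HM444103
MlHD60		insert(LP) 33		HM444135
MlHD70				HM444106
MlHD76a				HM444107
MlHD76b				HM444142
MlHD77a				HM444108
MlHD77b				HM444138
MlHD79		insert(N) 22		HM444109
MlHD86				HM444124
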