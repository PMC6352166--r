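strain	replicon	kind	is_name	complete	partial
NAR1	Ch	chromosome	ISTth3	0	1
NAR1	Ch	chromosome	ISTth4	5	0
NAR1	Ch	chromosome	ISTth6	1	0
NAR1	Ch	chromosome	ISTth7	13	0
NAR1	M1	megaplasmid	ISTth1	1	0
NAR1	M1	megaplasmid	ISTth3	1	0
NAR1	M1	megaplasmid	ISTth4	11	0
NAR1	M1	megaplasmid	ISTth6	0	1
NAR1	M1	megaplasmid	ISTth7	5	0
NAR1	M1	megaplasmid	IS1000A/B	0	2
NAR1	M2	megaplasmid	ISTth7	0	2
HB27	Ch	chromosome	ISTth2	2	0
HB27	Ch	chromosome	ISTth3	2	1
HB27	Ch	chromosome	ISTth5	1	0
HB27	Ch	chromosome	ISTth6	3	0
HB27	Ch	chromosome	ISTth7	2	2
HB27	Ch	chromosome	ISTth8	3	0
HB27	Ch	chromosome	IS1000A/B	1	8
HB27	pTT27	megaplasmid	ISTth1	1	0
HB27	pTT27	megaplasmid	ISTth2	1	0
HB27	pTT27	megaplasmid	ISTth3	1	0
HB27	pTT27	megaplasmid	ISTth5	1	0
HB27	pTT27	megaplasmid	ISTth6	1	0
HB27	pTT27	megaplasmid	ISTth7	4	1
HB27	pTT27	megaplasmid	ISTth8	1	1
HB27	pTT27	megaplasmid	IS1000A/B	1	34
HB8	Ch	chromosome	ISTth4	4	0
HB8	Ch	chromosome	ISTth6	1	0
HB8	Ch	chromosome	ISTth7	6	2
HB8	Ch	chromosome	IS1000A/B	1	14
HB8	pTT27	megaplasmid	ISTth4	4	0
HB8	pTT27	megaplasmid	ISTth6	1	1
HB8	pTT27	megaplasmid	ISTth7	1	2
HB8	pTT27	megaplasmid	ISTth8	2	0
HB8	pTT27	megaplasmid	IS1000A/B	3	39
HB8	pVV8	plasmid	ISTth1	1	0
HB8	pVV8	plasmid	ISTth3	0	1
HB8	pVV8	plasmid	ISTth4	2	0
HB8	pVV8	plasmid	ISTth6	1	0
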