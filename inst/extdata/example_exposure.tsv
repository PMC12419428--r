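SNP	CHR	BP	A1	A2	FREQ	BETA	SE	P	N
rs000001	1	1000000	A	G	0.31	0.052	0.009	7.6e-09	250000
rs000002	1	1200000	C	T	0.12	-0.044	0.011	6.3e-05	250000
rs000003	2	5400000	G	A	0.45	0.038	0.008	2.0e-06	250000
rs000004	7	8800000	T	C	0.27	0.041	0.009	5.2e-06	250000
rs000005	11	2200000	A	C	0.09	-0.061	0.014	1.3e-05	250000
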