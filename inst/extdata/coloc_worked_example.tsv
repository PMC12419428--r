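coloc_id	snp	V.df1	z.df1	r.df1	V.df2	z.df2	r.df2	internal.sum.lABF	snp_pp_h4
ebi-a-GCST011365;ukb-b-2393	rs12740374	8.12e-05	-11.74203928	0.997908885	1.10e-06	-0.693020819	0.999722037	61.85461925	0.854635972
ieu-a-7;ukb-b-2393	rs7528419	0.000131836	-9.974743076	0.999325679	1.10e-06	-0.799804585	0.999722868	42.28754878	0.716385554
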