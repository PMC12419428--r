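disease	outcome_id	exposure_id	exposure_label	or	or_lci95	or_uci95	pooled_or_published
Heart failure	ebi-a-GCST90018806	ukb-b-2393	balanced diet	0.231	0.118	0.451	0.194
Heart failure	finn-b-I9_HEARTFAIL_ALLCAUSE	ukb-b-2393	balanced diet	0.200	0.100	0.401	0.194
Heart failure	finn-b-I9_HEARTFAIL	ukb-b-2393	balanced diet	0.142	0.062	0.324	0.194
Heart failure	ebi-a-GCST90018806	ukb-b-5495	never eat sugar	2.804	1.206	6.519	3.099
Heart failure	finn-b-I9_HEARTFAIL_ALLCAUSE	ukb-b-5495	never eat sugar	4.020	1.451	11.139	3.099
Heart failure	finn-b-I9_HEARTFAIL	ukb-b-5495	never eat sugar	2.727	0.927	8.021	3.099
Coronary heart disease	ebi-a-GCST005195	ukb-b-2393	balanced diet	0.199	0.099	0.397	0.2
Coronary heart disease	ebi-a-GCST90013864	ukb-b-2393	balanced diet	0.135	0.057	0.322	0.2
Coronary heart disease	ieu-a-7	ukb-b-2393	balanced diet	0.246	0.132	0.461	0.2
Coronary heart disease	ebi-a-GCST005195	ukb-b-5495	never eat sugar	1.512	0.874	2.615	1.705
Coronary heart disease	ebi-a-GCST90013864	ukb-b-5495	never eat sugar	2.168	1.079	4.356	1.705
Coronary heart disease	ieu-a-7	ukb-b-5495	never eat sugar	1.620	0.773	3.394	1.705
Myocardial infarction	ebi-a-GCST90018877	ukb-b-2393	balanced diet	0.195	0.098	0.386	0.96
Myocardial infarction	finn-b-I9_MI	ukb-b-2393	balanced diet	0.199	0.063	0.628	0.96
Myocardial infarction	ebi-a-GCST011365	ukb-b-2393	balanced diet	0.185	0.106	0.323	0.96
Myocardial infarction	ebi-a-GCST90038610	ukb-b-2393	balanced diet	0.964	0.946	0.982	0.96
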