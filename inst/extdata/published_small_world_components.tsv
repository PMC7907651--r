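network	t_net	t_rand	asl_net	asl_rand	s_published
drought	0.027	0.017	2.842	2.716	1.533
salt	0.042	0.012	3.329	3.011	3.118
cold	0.022	0.014	3.020	2.755	1.403
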