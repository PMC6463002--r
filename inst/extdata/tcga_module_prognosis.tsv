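module	os_hr	os_ci_low	os_ci_high	os_p	pfi_hr	pfi_ci_low	pfi_ci_high	pfi_p
BLCA_M1	0.57	0.41	0.78	0.00052	0.67	0.48	0.91	0.011
BLCA_M2	1.78	1.29	2.48	0.00044	1.42	1.04	1.95	0.027
BLCA_M4	0.75	0.54	1.03	0.076	0.70	0.51	0.97	0.029
KIRC_M1	2.04	1.46	2.84	2e-05	1.24	0.89	1.74	0.2
KIRC_M2	0.50	0.36	0.70	3.5e-05	0.77	0.55	1.08	0.12
LIHC_M1	2.06	1.41	3.02	0.00013	1.32	0.96	1.82	0.085
LIHC_M2	0.50	0.34	0.73	0.00023	0.79	0.57	1.08	0.14
LUAD_M1	0.63	0.45	0.87	0.0043	0.74	0.55	1.01	0.054
LUAD_M3	1.86	1.34	2.58	0.00018	1.42	1.05	1.93	0.023
LUSC_M2	0.75	0.55	1.01	0.059	0.80	0.56	1.15	0.22
LUSC_M3	0.77	0.57	1.05	0.099	0.98	0.69	1.41	0.93
PRAD_M1	6.42	0.78	52.60	0.049	1.80	1.16	2.79	0.0081
PRAD_M2	0.42	0.08	2.19	0.29	0.52	0.33	0.81	0.0032
THCA_M1	1.21	0.45	3.23	0.7	0.55	0.31	0.99	0.041
UCEC_M3	1.81	1.15	2.84	0.0087	1.66	1.12	2.47	0.01
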