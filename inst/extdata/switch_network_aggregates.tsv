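matrix	label	sum_pos	n_corr	n_pos	n_matrix	C	C_digits	S_M	S_M_digits	mutation_network
FliM_M.FliG_MC	randomized	17621.4	116900	53348	152100	1	0	1	0	FALSE
FliM_M.FliG_MC	FliM_M.FliG_MC	19808.8	58534	36892	152100	0.5	1	1.63	2	FALSE
FliM_M.FliG_MC	FliM_M	9776.6	24142	16538	33124	0.95	2	1.79	2	FALSE
FliM_M.FliG_MC	FliG_MC	9315.9	22558	16622	43264	0.68	2	1.7	1	FALSE
FliM_M.FliG_MC	FliM_M-FliG_MC_inter	716	11834	3732	36764	0.42	2	0.58	2	FALSE
FliM_M.FliG_MC	FliM_M-FliG_M_contact	11.1	136	40	825	0.21	2	0.84	2	FALSE
FliM_M.FliG_MC	FliM_M-FliG_C_contact	4.8	68	30	625	0.14	2	0.48	2	FALSE
FliM_M.FliG_MC	FliM_M_CW	658.5	1206	860	1444	1.09	2	2.09	2	TRUE
FliM_M.FliG_MC	FliM_M_CCW	145.1	284	202	361	1.02	2	1.96	2	TRUE
FliG	randomized	11423.3	76887	34532	103041	1	0	1	0	FALSE
FliG	FliG	9314.1	38918	22882	103041	0.5	1	1.23	2	FALSE
FliG	FliG_N1-4	623.2	2134	1402	4356	0.66	2	1.34	2	FALSE
FliG	FliG_C3-6	832.5	2300	1466	3969	0.78	2	1.72	2	FALSE
FliG	FliG_ARM-M	485.7	1470	928	2601	0.76	2	1.58	2	FALSE
FliG	FliG_ARM-C	79.1	236	166	1681	0.19	2	1.44	2	FALSE
FliG	FliG_M-FliG_C_inter	810.4	4002	2201	17010	0.32	2	1.11	2	FALSE
FliG	FliG_N-FliG_M_inter	745.1	3563	2033	8505	0.56	2	1.11	2	FALSE
FliG	FliG_N-FliG_MC_inter	1564.9	8019	4484	22155	0.48	2	1.06	2	FALSE
FliG	FliG_M-FliG_C_contact	45.9	200	117	576	0.46	2	1.18	2	FALSE
FliG	FliG_N-FliG_M_3node	77.2	264	155	432	0.82	2	1.51	2	FALSE
FliG	FliG_M-FliG_C_3node	102.3	264	148	432	0.82	2	2.09	2	FALSE
FliG	FliG_C_3node	128.8	290	200	432	0.9	1	1.95	2	FALSE
FliG	FliG_MC_3node_CW	33.7	110	66	256	0.57	2	1.54	2	TRUE
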