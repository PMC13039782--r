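valve	dobutamine	cycle_time	dp_mean	q_exp	q_exp_unc	q_sim	q_sim_sd	ava_exp	ava_exp_lo	ava_exp_hi	ava_sim	ava_sim_lo	ava_sim_hi
non-calcified	d0	0.80	44	143	14	149	2	0.40	0.39	0.44	0.44	0.43	0.45
non-calcified	d5	0.76	52	219	22	222	5	0.67	0.63	0.71	0.69	0.68	0.69
non-calcified	d10	0.70	51	228	23	209	4	0.78	0.73	0.82	0.63	0.62	0.64
non-calcified	d20	0.57	53	215	22	228	4	0.73	0.68	0.77	0.77	0.76	0.77
calcified	d0	0.80	77	137	14	154	8	0.39	0.33	0.44	0.37	0.35	0.37
calcified	d5	0.76	89	216	22	205	8	0.51	0.44	0.58	0.50	0.49	0.52
calcified	d10	0.70	87	226	23	208	5	0.48	0.41	0.54	0.55	0.53	0.56
calcified	d20	0.57	85	214	21	201	7	0.57	0.49	0.64	0.54	0.53	0.55
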