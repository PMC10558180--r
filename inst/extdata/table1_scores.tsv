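case_id	cell_line	gd_status	modality	volume_mm3	sensitivity	specificity	dice	max_surface_distance_mm
TB01	GB126	TRUE	T1	122	0.74	0.99	0.84	1.6
TB01	GB126	TRUE	T2	101	0.62	1	0.76	1.8
TB01	GB126	TRUE	T1+T2	128	0.77	0.99	0.86	1.6
TB01	GB126	TRUE	PET	185	0.87	0.91	0.81	2
TB01	GB126	TRUE	MRI+PET	191	0.91	0.91	0.83	2
TB01	GB126	TRUE	Optical	161	nd	nd	nd	nd
TB02	GB126	TRUE	T1	61	0.68	1	0.8	1.1
TB02	GB126	TRUE	T2	52	0.59	1	0.74	1.1
TB02	GB126	TRUE	T1+T2	63	0.7	1	0.81	1.1
TB02	GB126	TRUE	PET	112	0.84	0.93	0.73	2
TB02	GB126	TRUE	MRI+PET	117	0.89	0.93	0.75	2
TB02	GB126	TRUE	Optical	86	nd	nd	nd	nd
TB03	GB126	TRUE	T1	69	0.53	0.99	0.68	2.6
TB03	GB126	TRUE	T2	58	0.44	0.99	0.6	2.9
TB03	GB126	TRUE	T1+T2	81	0.61	0.99	0.74	2.6
TB03	GB126	TRUE	PET	151	0.9	0.92	0.81	1.8
TB03	GB126	TRUE	MRI+PET	153	0.91	0.92	0.81	1.8
TB03	GB126	TRUE	Optical	124	nd	nd	nd	nd
TB04	U87	TRUE	T1	89	0.76	0.99	0.82	1.2
TB04	U87	TRUE	T2	122	0.79	0.94	0.72	2.1
TB04	U87	TRUE	T1+T2	133	0.84	0.93	0.74	2.1
TB04	U87	TRUE	PET	211	0.93	0.82	0.61	2.3
TB04	U87	TRUE	MRI+PET	226	0.95	0.8	0.6	2.3
TB04	U87	TRUE	Optical	104	nd	nd	nd	nd
TB05	GB187	FALSE	T1	0	0	1	0	nd
TB05	GB187	FALSE	T2	72	0.53	0.97	0.63	2.7
TB05	GB187	FALSE	T1+T2	72	0.53	0.97	0.63	2.7
TB05	GB187	FALSE	PET	161	0.85	0.88	0.67	2.8
TB05	GB187	FALSE	MRI+PET	172	0.89	0.87	0.67	2.8
TB05	GB187	FALSE	Optical	104	nd	nd	nd	nd
TB06	GB187	FALSE	T1	0	0	1	0	nd
TB06	GB187	FALSE	T2	60	0.52	0.96	0.58	3.2
TB06	GB187	FALSE	T1+T2	60	0.52	0.96	0.58	3.2
TB06	GB187	FALSE	PET	87	0.56	0.91	0.53	3.1
TB06	GB187	FALSE	MRI+PET	109	0.73	0.9	0.6	3.1
TB06	GB187	FALSE	Optical	76	nd	nd	nd	nd
TB07	GB187	FALSE	T1	0	0	1	0	nd
TB07	GB187	FALSE	T2	28	0.73	0.97	0.76	1.2
TB07	GB187	FALSE	T1+T2	28	0.73	0.97	0.76	1.2
TB07	GB187	FALSE	PET	29	0.46	0.93	0.47	2
TB07	GB187	FALSE	MRI+PET	47	0.88	0.91	0.69	2
TB07	GB187	FALSE	Optical	30	nd	nd	nd	nd
TB08	GB187	FALSE	T1	0	0	1	0	nd
TB08	GB187	FALSE	T2	60	0.63	0.96	0.64	1.8
TB08	GB187	FALSE	T1+T2	60	0.63	0.96	0.64	1.8
TB08	GB187	FALSE	PET	69	0.67	0.95	0.63	2.4
TB08	GB187	FALSE	MRI+PET	89	0.8	0.93	0.66	2.4
TB08	GB187	FALSE	Optical	63	nd	nd	nd	nd
TB09	U251	FALSE	T1	0	0	1	0	nd
TB09	U251	FALSE	T2	94	0.71	0.89	0.58	2.4
TB09	U251	FALSE	T1+T2	94	0.71	0.89	0.58	2.4
TB09	U251	FALSE	PET	120	0.82	0.84	0.57	2.4
TB09	U251	FALSE	MRI+PET	133	0.86	0.82	0.56	2.4
TB09	U251	FALSE	Optical	64	nd	nd	nd	nd
TB10	U251	FALSE	T1	0	0	1	0	nd
TB10	U251	FALSE	T2	8	0.24	0.99	0.35	3.1
TB10	U251	FALSE	T1+T2	8	0.24	0.99	0.35	3.1
TB10	U251	FALSE	PET	0	0	1	0	nd
TB10	U251	FALSE	MRI+PET	8	0.24	0.99	0.35	3.1
TB10	U251	FALSE	Optical	22	nd	nd	nd	nd
TB11	GB7	FALSE	T1	0	0	1	0	nd
TB11	GB7	FALSE	T2	71	0.37	0.97	0.47	7.6
TB11	GB7	FALSE	T1+T2	71	0.37	0.97	0.47	7.6
TB11	GB7	FALSE	PET	0	0	1	0	nd
TB11	GB7	FALSE	MRI+PET	71	0.37	0.97	0.47	7.6
TB11	GB7	FALSE	Optical	132	nd	nd	nd	nd
TB12	GB7	FALSE	T1	0	0	1	0	nd
TB12	GB7	FALSE	T2	39	0.21	0.98	0.32	8.6
TB12	GB7	FALSE	T1+T2	39	0.21	0.98	0.32	8.6
TB12	GB7	FALSE	PET	0	0	1	0	nd
TB12	GB7	FALSE	MRI+PET	39	0.21	0.98	0.32	8.6
TB12	GB7	FALSE	Optical	131	nd	nd	nd	nd
TB13	GB94	FALSE	T1	0	0	1	0	nd
TB13	GB94	FALSE	T2	57	0.35	0.93	0.18	4.7
TB13	GB94	FALSE	T1+T2	57	0.35	0.93	0.18	4.7
TB13	GB94	FALSE	PET	0	0	1	0	nd
TB13	GB94	FALSE	MRI+PET	57	0.35	0.93	0.18	4.7
TB13	GB94	FALSE	Optical	20	nd	nd	nd	nd
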