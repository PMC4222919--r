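plot	location	nu_sp_0	nu_sp_2	nu_sp_inf	nu_mean2_Picea	nu_mean2_Pinus	nu_mean2_Populus	nu_mean2_Pseudotsuga
TN	La Tinaja	6	2.75	2.30	1.551	1.237	1.417	NA
RC	El Ranchito	6	3.85	2.42	1.567	1.596	1.719	NA
CV	El Cuervo	5	3.48	2.56	1.597	1.596	NA	NA
TY	Talayote	7	3.15	2.07	1.564	1.575	NA	1.383
TR	Las Trojas	8	4.24	2.70	1.577	1.349	1.510	NA
VN	El Venado	8	4.12	2.41	1.565	1.667	NA	NA
LQ	La Quebrada	6	3.70	2.67	1.485	1.579	1.414	NA
PPR	Paraje Piedra Rayada	4	2.29	1.65	1.430	1.417	1.299	1.590
QD	Quebrada de los Duran	5	2.04	1.49	1.459	1.721	1.231	1.540
CB	Cebollitas	7	4.34	2.59	1.525	1.536	NA	1.696
SJ	San Jose de las Causas	7	4.46	3.00	1.448	1.654	NA	NA
SB	Santa Barbara	9	2.90	1.86	1.439	NA	NA	1.740
ACH	Arroyo del Chino	4	3.44	2.73	1.491	1.574	NA	1.685
LP	La Pista	5	1.92	1.49	1.511	NA	1.333	NA
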