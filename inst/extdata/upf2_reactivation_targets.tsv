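fbgn	gene_name	fold_up	de_p	relative_slope	relative_slope_p	fold_decay_4h
FBgn0040837	CG8620	11.84	2.38E-13	-0.26	0.039	2.44
FBgn0034605	CG15661	8.84	1.39E-03	-0.43	0.082	2.20
FBgn0033240	CG2906	7.30	1.95E-07	-0.08	0.043	1.80
FBgn0029766	CG15784	6.52	1.29E-16	-0.40	0.040	2.42
FBgn0261113	Xrp1	6.52	3.51E-17	-0.39	0.041	1.94
FBgn0019890	Smg5	5.33	5.90E-05	-0.54	0.044	2.44
FBgn0033153	Gadd45	5.00	2.23E-06	-0.70	0.040	4.82
FBgn0039319	CG13659	4.85	1.84E-10	0.00	0.081	2.37
FBgn0037936	CG6908	4.50	1.18E-11	-0.68	0.039	5.21
FBgn0034501	CG13868	4.33	9.15E-11	-0.34	0.042	2.12
FBgn0014031	Spat	4.19	2.24E-10	-0.15	0.087	2.68
FBgn0031643	CG3008	3.94	4.97E-09	-0.14	0.043	1.85
FBgn0041627	Ku80	3.58	1.49E-05	-0.26	0.040	1.85
FBgn0032981	CG3635	3.34	4.00E-03	-0.19	0.077	2.06
FBgn0037391	CG2017	3.34	1.11E-04	-0.20	0.034	2.32
FBgn0050424	CG30424	3.31	1.11E-03	-0.46	0.082	2.34
FBgn0039328	CHKov2	3.14	3.11E-05	-0.44	0.036	2.66
FBgn0039260	Smg6	2.88	3.13E-05	-0.46	0.039	2.07
FBgn0035476	CG12766	2.70	1.47E-04	-0.54	0.076	2.16
FBgn0042105	CG18748	2.60	3.14E-03	-0.72	0.075	7.18
FBgn0086370	sra	2.59	8.02E-05	-0.11	0.082	1.87
FBgn0037781	Fancl	2.51	1.58E-03	-0.23	0.083	2.31
FBgn0085194	CG34165	2.13	3.54E-03	-0.11	0.049	1.81
FBgn0039226	Ude	1.91	7.12E-03	-0.50	0.088	2.20
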