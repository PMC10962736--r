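human_gene	study1	study2	study3
PHGDH	2.5	3.1	2.9
PSAT1	2.2	2.8	2.4
PYCR1	3	2.1	2.6
ASNS	2.4	2	2.3
PCK2	2.1	2.5	2.2
SLC7A11	4	3.2	2.8
SLC7A1	2.3	2.2	2.1
FGF21	2	2	2
MTHFD2	3.5	2.9	3.3
CHAC1	2.6	2.4	2.9
SHMT2	2.2	2.6	2.4
CORE_12	3	2	0.9
CORE_13	2.5	NA	1.2
CORE_14	1.71	1.73	1.01
CORE_15	1.61	1.41	1.27
CORE_16	1.51	0.85	1.42
CORE_17	1.48	1.2	1.49
CORE_18	1.73	0.98	1.21
CORE_19	1.73	1.78	0.83
CORE_20	1.22	1.32	1.69
CORE_21	0.85	1.79	1.74
CORE_22	0.79	1.27	1.13
CORE_23	1.7	1.19	1.62
CORE_24	1.51	1.59	1.13
CORE_25	1.45	0.7	1.62
CORE_26	0.71	0.93	1.7
CORE_27	1.37	1.12	1.18
CORE_28	0.74	1.77	1.17
CORE_29	1.75	1.68	1.4
CORE_30	1.77	1.38	1.07
CORE_31	1.08	1.14	1.56
CORE_32	0.74	1.52	1.45
CORE_33	0.89	0.99	1.27
CORE_34	1.44	1.78	1.54
CORE_35	1.32	1.63	0.91
CORE_36	1	1.61	1.46
CORE_37	0.96	0.75	0.85
CORE_38	0.94	1.23	0.92
CORE_39	1.49	0.71	1.11
CORE_40	1.27	0.7	1.34
CORE_41	0.87	1.09	1.41
CORE_42	1.55	1.32	0.96
CORE_43	0.8	0.79	1.04
CORE_44	1.43	0.7	0.93
CORE_45	1.73	1.72	1.51
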