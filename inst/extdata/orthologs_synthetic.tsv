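mouse_gene	human_gene
Phgdh	PHGDH
Psat1	PSAT1
Pycr1	PYCR1
Asns	ASNS
Pck2	PCK2
Slc7a11	SLC7A11
Slc7a1	SLC7A1
Fgf21	FGF21
Mthfd2	MTHFD2
Chac1	CHAC1
Shmt2	SHMT2
core_12	CORE_12
core_13	CORE_13
core_14	CORE_14
core_15	CORE_15
core_16	CORE_16
core_17	CORE_17
core_18	CORE_18
core_19	CORE_19
core_20	CORE_20
core_21	CORE_21
core_22	CORE_22
core_23	CORE_23
core_24	CORE_24
core_25	CORE_25
core_26	CORE_26
core_27	CORE_27
core_28	CORE_28
core_29	CORE_29
core_30	CORE_30
core_31	CORE_31
core_32	CORE_32
core_33	CORE_33
core_34	CORE_34
core_35	CORE_35
core_36	CORE_36
core_37	CORE_37
core_38	CORE_38
core_39	CORE_39
core_40	CORE_40
core_41	CORE_41
core_42	CORE_42
core_43	CORE_43
core_44	CORE_44
core_45	CORE_45
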