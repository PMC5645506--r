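rsid	disease	risk	trait	gwas_gene	gene	tissue	slope	low_rpkm
rs507506	type_2_diabetes	positive	Adiponectin levels	DLG4	ACADVL	adipose_subcutaneous	-0.20	FALSE
rs507506	type_2_diabetes	positive	Adiponectin levels	DLG4	CLDN7	adipose_subcutaneous	-0.36	FALSE
rs507506	type_2_diabetes	positive	Adiponectin levels	DLG4	CLDN7	adipose_visceral	-0.44	FALSE
rs507506	type_2_diabetes	positive	Adiponectin levels	DLG4	CLDN7	skeletal_muscle	-0.56	TRUE
rs174541	type_2_diabetes	positive	Metabolite levels	FEN1-FADS1	FADS1	skeletal_muscle	-0.21	FALSE
rs174541	type_2_diabetes	positive	Metabolite levels	FEN1-FADS1	FADS1	pancreas	-0.70	FALSE
rs174550	type_2_diabetes	positive	Fasting glucose-related	FADS1	FADS1	skeletal_muscle	-0.20	FALSE
rs174550	type_2_diabetes	positive	Fasting glucose-related	FADS1	FADS1	pancreas	-0.73	FALSE
rs7945071	type_2_diabetes	positive	Cognitive function	LOC105369486	FDX1	adipose_visceral	0.23	FALSE
rs2290402	type_2_diabetes	positive	Type 2 diabetes	TMEM175	IDUA	adipose_visceral	-0.41	FALSE
rs2290402	type_2_diabetes	positive	Type 2 diabetes	TMEM175	IDUA	skeletal_muscle	-0.29	FALSE
rs1515110	type_2_diabetes	positive	Adiponectin levels	LOC646736-LOC105373913	IRS1	adipose_subcutaneous	-0.26	FALSE
rs2943640	type_2_diabetes	positive	Type 2 diabetes	LOC646736-LOC105373913	IRS1	adipose_subcutaneous	-0.31	FALSE
rs2943641	type_2_diabetes	positive	Type 2 diabetes and other traits	LOC646736-LOC105373913	IRS1	adipose_subcutaneous	-0.29	FALSE
rs925735	type_2_diabetes	positive	Adiponectin levels	LOC105373913-LOC105373915	IRS1	adipose_subcutaneous	-0.27	FALSE
rs10510110	type_2_diabetes	positive	Type 2 diabetes	PLEKHA1-LOC105378525	PLEKHA1	adipose_subcutaneous	-0.20	FALSE
rs10510110	type_2_diabetes	positive	Type 2 diabetes	PLEKHA1-LOC105378525	PLEKHA1	skeletal_muscle	-0.14	FALSE
rs7493	type_2_diabetes	positive	Yu-Zhi constitution type in type 2 diabetes	PON2	PON2	skeletal_muscle	-0.28	FALSE
rs7493	type_2_diabetes	positive	Yu-Zhi constitution type in type 2 diabetes	PON2	PON2	pancreas	-0.37	FALSE
rs849134	type_2_diabetes	negative	Type 2 diabetes	JAZF1	JAZF1	adipose_subcutaneous	0.20	FALSE
rs849134	type_2_diabetes	negative	Type 2 diabetes	JAZF1	JAZF1	adipose_visceral	0.25	FALSE
rs849134	type_2_diabetes	negative	Type 2 diabetes	JAZF1	JAZF1	skeletal_muscle	0.27	FALSE
rs849134	type_2_diabetes	negative	Type 2 diabetes	JAZF1	JAZF1	pancreas	0.52	FALSE
rs849135	type_2_diabetes	negative	Type 2 diabetes	JAZF1	JAZF1	adipose_subcutaneous	0.20	FALSE
rs849135	type_2_diabetes	negative	Type 2 diabetes	JAZF1	JAZF1	adipose_visceral	0.25	FALSE
rs849135	type_2_diabetes	negative	Type 2 diabetes	JAZF1	JAZF1	skeletal_muscle	0.27	FALSE
rs849135	type_2_diabetes	negative	Type 2 diabetes	JAZF1	JAZF1	pancreas	0.52	FALSE
rs864745	type_2_diabetes	negative	Type 2 diabetes	JAZF1	JAZF1	adipose_subcutaneous	0.20	FALSE
rs864745	type_2_diabetes	negative	Type 2 diabetes	JAZF1	JAZF1	adipose_visceral	0.24	FALSE
rs864745	type_2_diabetes	negative	Type 2 diabetes	JAZF1	JAZF1	skeletal_muscle	0.27	FALSE
rs864745	type_2_diabetes	negative	Type 2 diabetes	JAZF1	JAZF1	pancreas	0.51	FALSE
rs2290402	type_2_diabetes	negative	Type 2 diabetes	TMEM175	DGKQ	adipose_subcutaneous	-0.30	FALSE
rs507506	type_2_diabetes	negative	Adiponectin levels	DLG4	CTDNEP1	adipose_subcutaneous	0.21	FALSE
rs2230061	obesity	positive	Fat body mass	CTSS	ARNT	adipose_visceral	0.19	FALSE
rs2230061	obesity	positive	Fat body mass	CTSS	CTSS	adipose_subcutaneous	0.17	FALSE
rs2230061	obesity	positive	Fat body mass	CTSS	CTSS	skeletal_muscle	0.29	TRUE
rs2230061	obesity	positive	Fat body mass	CTSS	CTSS	pancreas	0.33	FALSE
rs8050907	obesity	positive	Obesity-related traits	PKD2L1	HMOX2	skeletal_muscle	0.66	FALSE
rs10540	obesity	positive	Body mass index	RNH1	HRAS	adipose_subcutaneous	-0.31	FALSE
rs10540	obesity	positive	Body mass index	RNH1	HRAS	skeletal_muscle	-0.24	FALSE
rs2176040	obesity	positive	Body mass index	LOC646736-LOC105373913	IRS1	adipose_subcutaneous	-0.29	FALSE
rs4144743	obesity	positive	Body mass index	MYL4-ITGB3	ITGB3	adipose_subcutaneous	-0.33	FALSE
rs4144743	obesity	positive	Body mass index	MYL4-ITGB3	ITGB3	skeletal_muscle	-0.31	TRUE
rs1805081	obesity	positive	Obesity	NPC1	NPC1	adipose_subcutaneous	0.54	FALSE
rs1805081	obesity	positive	Obesity	NPC1	NPC1	adipose_visceral	0.45	FALSE
rs1805081	obesity	positive	Obesity	NPC1	NPC1	skeletal_muscle	0.14	FALSE
rs1805081	obesity	positive	Obesity	NPC1	NPC1	pancreas	0.40	FALSE
rs1808579	obesity	positive	Body mass index	C18orf8-NPC1	NPC1	adipose_subcutaneous	0.45	FALSE
rs1808579	obesity	positive	Body mass index	C18orf8-NPC1	NPC1	adipose_visceral	0.37	FALSE
rs1808579	obesity	positive	Body mass index	C18orf8-NPC1	NPC1	skeletal_muscle	0.13	FALSE
rs1808579	obesity	positive	Body mass index	C18orf8-NPC1	NPC1	pancreas	0.38	FALSE
rs4888671	obesity	positive	Obesity-related traits	NUDT7-VAT1L	NUDT7	adipose_subcutaneous	0.44	FALSE
rs4888671	obesity	positive	Obesity-related traits	NUDT7-VAT1L	NUDT7	adipose_visceral	0.46	FALSE
rs4888671	obesity	positive	Obesity-related traits	NUDT7-VAT1L	NUDT7	pancreas	0.58	FALSE
rs11247915	obesity	positive	Obesity-related traits	ALLC-LOC105373393	PIGV	skeletal_muscle	-0.2	FALSE
rs10540	obesity	positive	Body mass index	RNH1	PTDSS2	adipose_subcutaneous	-0.36	FALSE
rs10540	obesity	positive	Body mass index	RNH1	PTDSS2	adipose_visceral	-0.43	FALSE
rs10540	obesity	positive	Body mass index	RNH1	PTDSS2	skeletal_muscle	-0.36	FALSE
rs2650492	obesity	positive	Body mass index	SBK1	SULT1A1	skeletal_muscle	-0.29	FALSE
rs2650492	obesity	positive	Body mass index	SBK1	SULT1A1	pancreas	-0.51	FALSE
rs17001654	obesity	negative	Body mass index	SCARB2	NAAA	adipose_subcutaneous	0.35	FALSE
rs7503807	obesity	negative	Obesity	RPTOR	RPTOR	skeletal_muscle	0.16	FALSE
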