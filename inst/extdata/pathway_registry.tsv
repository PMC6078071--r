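pathway	step_index	enzyme	component	kind	koids	compartment	substrate	product	note
heme_C5	1	GTR	GTR	enzyme	K02492	nucleus_encoded	glutamyl-tRNA	glutamate-1-semialdehyde	glutamyl-tRNA reductase (hemA)
heme_C5	2	GSAT	GSAT	enzyme	K01845	nucleus_encoded	glutamate-1-semialdehyde	5-aminolevulinate	glutamate-1-semialdehyde 2,1-aminomutase (hemL)
heme_C5	3	ALAD	ALAD	enzyme	K01698	nucleus_encoded	5-aminolevulinate	porphobilinogen	aminolevulinic acid dehydratase (hemB)
heme_C5	4	PBGD	PBGD	enzyme	K01749	nucleus_encoded	porphobilinogen	hydroxymethylbilane	porphobilinogen deaminase (hemC)
heme_C5	5	UROS	UROS	enzyme	K01719	nucleus_encoded	hydroxymethylbilane	uroporphyrinogen III	uroporphyrinogen III synthase (hemD)
heme_C5	6	UROD	UROD	enzyme	K01599	nucleus_encoded	uroporphyrinogen III	coproporphyrinogen III	uroporphyrinogen decarboxylase (hemE)
heme_C5	7	CPOX	hemN	alternative	K02495	nucleus_encoded	coproporphyrinogen III	protoporphyrinogen IX	oxygen-independent coproporphyrinogen oxidase
heme_C5	7	CPOX	hemF	alternative	K00228	nucleus_encoded	coproporphyrinogen III	protoporphyrinogen IX	oxygen-dependent coproporphyrinogen oxidase
heme_C5	8	PPOX	hemY	alternative	K00231	nucleus_encoded	protoporphyrinogen IX	protoporphyrin IX	hemY-type protoporphyrinogen IX oxidase
heme_C5	8	PPOX	hemJ	alternative		nucleus_encoded	protoporphyrinogen IX	protoporphyrin IX	hemJ-type PPOX; not registered in the current KEGG pathway (query: Synechocystis slr1790, UniProtKB P72793)
heme_C5	9	FeCH	FeCH	enzyme	K01772	nucleus_encoded	protoporphyrin IX	protoheme	ferrochelatase (hemH)
chlorophyll_a	1	MgCH	ChlD	subunit	K03404	nucleus_encoded	protoporphyrin IX	Mg-protoporphyrin IX	Mg chelatase subunit D; classified independently
chlorophyll_a	1	MgCH	ChlH	subunit	K03403	nucleus_encoded	protoporphyrin IX	Mg-protoporphyrin IX	Mg chelatase subunit H; classified independently
chlorophyll_a	1	MgCH	ChlI	subunit	K03405	plastid_encoded	protoporphyrin IX	Mg-protoporphyrin IX	Mg chelatase subunit I; plastid-encoded in study taxa, excluded from nuclear-origin analysis
chlorophyll_a	2	MgPMT	MgPMT	enzyme	K03428	nucleus_encoded	Mg-protoporphyrin IX	Mg-protoporphyrin IX monomethyl ester	S-adenosylmethionine:Mg-protoporphyrin O-methyltransferase (chlM)
chlorophyll_a	3	MgPME_cyclase	multi_subunit	alternative	K04035	unknown	Mg-protoporphyrin IX monomethyl ester	divinyl protochlorophyllide	aerobic multi-subunit cyclase; not detected in study taxa
chlorophyll_a	3	MgPME_cyclase	chlE	alternative	K04034	unknown	Mg-protoporphyrin IX monomethyl ester	divinyl protochlorophyllide	single-subunit cyclase (chlE); not detected in study taxa
chlorophyll_a	4	DVR	N-DVR	alternative	K19073	nucleus_encoded	divinyl protochlorophyllide	protochlorophyllide	NADPH-dependent divinyl reductase; shares KOID K19073 with F-DVR
chlorophyll_a	4	DVR	F-DVR	alternative	K19073	nucleus_encoded	divinyl protochlorophyllide	protochlorophyllide	ferredoxin-dependent divinyl reductase; shares KOID K19073 with N-DVR
chlorophyll_a	5	POR	por	alternative	K00218	nucleus_encoded	protochlorophyllide	chlorophyllide a	light-dependent protochlorophyllide reductase
chlorophyll_a	5	POR	chlB/chlL/chlN	alternative	K04037,K04038,K04039	plastid_encoded	protochlorophyllide	chlorophyllide a	light-independent POR; three plastid-encoded subunits
chlorophyll_a	6	CS	CS	enzyme	K04040	nucleus_encoded	chlorophyllide a	chlorophyll a	chlorophyll synthase (chlG)
non_mevalonate	1	DXS	DXS	enzyme	K01662	nucleus_encoded	pyruvate + glyceraldehyde 3-phosphate	1-deoxy-D-xylulose 5-phosphate	DXP synthase
non_mevalonate	2	DXR	DXR	enzyme	K00099	nucleus_encoded	1-deoxy-D-xylulose 5-phosphate	2-C-methyl-D-erythritol 4-phosphate	DXP reductoisomerase
non_mevalonate	3	IspD	IspD	enzyme	K00991	nucleus_encoded	2-C-methyl-D-erythritol 4-phosphate	CDP-ME	MEP cytidylyltransferase
non_mevalonate	4	IspE	IspE	enzyme	K00919	nucleus_encoded	CDP-ME	CDP-MEP	CDP-ME kinase
non_mevalonate	5	IspF	IspF	enzyme	K01770	nucleus_encoded	CDP-MEP	MEcPP	MEcPP synthase
non_mevalonate	6	IspG	IspG	enzyme	K03526	nucleus_encoded	MEcPP	HMB-PP	HMB-PP synthase
non_mevalonate	7	IspH	IspH	enzyme	K03527	nucleus_encoded	HMB-PP	isopentenyl diphosphate	HMB-PP reductase
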