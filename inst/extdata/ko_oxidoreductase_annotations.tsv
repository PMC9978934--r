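ko_id	symbol	description	ec_numbers	nadp_dependent
K08977	cruF	bisanhydrobacterioruberin hydratase	4.2.1.161	FALSE
K02538	manR	mannose operon transcriptional activator		FALSE
K16788	niaX	niacin transporter		FALSE
K03973	pspC	phage shock protein C		FALSE
K01224	E3.2.1.89	arabinogalactan endo-1,4-beta-galactosidase	3.2.1.89	FALSE
K00325	pntB	H+-translocating NAD(P) transhydrogenase subunit beta	1.6.1.2 7.1.1.1	TRUE
K02791	malX	maltose/glucose PTS system EIICB component	2.7.1.199 2.7.1.208	FALSE
K11646	K11646	3-dehydroquinate synthase II	1.4.1.24	FALSE
K14660	nodE	nodulation protein E	2.3.1.-	FALSE
K00324	pntA	H+-translocating NAD(P) transhydrogenase subunit alpha	1.6.1.2 7.1.1.1	TRUE
K03339	iolJ	6-phospho-5-dehydro-2-deoxy-D-gluconate aldolase	4.1.2.29	FALSE
K09163	K09163	uncharacterized protein		FALSE
K00197	cdhE	acetyl-CoA decarbonylase/synthase complex subunit gamma	2.1.1.245	FALSE
K15023	acsE	5-methyltetrahydrofolate corrinoid/iron sulfur protein methyltransferase	2.1.1.258	FALSE
K11261	fwdE	formylmethanofuran dehydrogenase subunit E	1.2.7.12	TRUE
K03389	hdrB2	heterodisulfide reductase subunit B2	1.8.7.3 1.8.98.4 1.8.98.5 1.8.98.6	FALSE
K00198	cooS	anaerobic carbon-monoxide dehydrogenase catalytic subunit	1.2.7.4	TRUE
K15051	endA	DNA-entry nuclease		FALSE
K02173	yggC	P-loop NTPase domain-containing protein YggC		FALSE
K02750	glvC	alpha-glucoside PTS system EIICB component	2.7.1.208 2.7.1.-	FALSE
K13677	dgs	1,2-diacylglycerol-3-alpha-glucose alpha-1,2-glucosyltransferase	2.4.1.208	FALSE
K00105	E1.1.3.21	alpha-glycerophosphate oxidase	1.1.3.21	FALSE
K02530	lacR	DeoR family transcriptional regulator, lactose phosphotransferase system repressor		FALSE
K08325	yqhD	NADP-dependent alcohol dehydrogenase	1.1.1.2	TRUE
K10530	lctO	L-lactate oxidase	1.1.3.2	FALSE
K18217	steB	ATP-binding cassette subfamily B tetracycline resistant protein		FALSE
K09952	cas9	CRISPR-associated endonuclease Csn1	3.1.-.-	FALSE
K03390	hdrC2	heterodisulfide reductase subunit C2	1.8.7.3 1.8.98.4 1.8.98.5 1.8.98.6	FALSE
K02291	crtB	15-cis-phytoene synthase	2.5.1.32	FALSE
K01215	dexB	glucan 1,6-alpha-glucosidase	3.2.1.70	FALSE
K06896	mapP	maltose 6'-phosphate phosphatase	3.1.3.90	FALSE
K02779	ptsG	glucose PTS system EIICB component	2.7.1.199	FALSE
K01071	MCH	medium-chain acyl-[acyl-carrier-protein] hydrolase	3.1.2.21	FALSE
K09758	asdA	aspartate 4-decarboxylase	4.1.1.12	FALSE
K02781	srlB	glucitol/sorbitol PTS system EIIA component	2.7.1.198	FALSE
K07078	FRM2	type II nitroreductase		FALSE
K03388	hdrA2	heterodisulfide reductase subunit A2	1.8.7.3 1.8.98.4 1.8.98.5 1.8.98.6	FALSE
K18981	udh	uronate dehydrogenase	1.1.1.203	TRUE
K15780	tilS-hprT	bifunctional protein TilS/HprT	6.3.4.19 2.4.2.8	FALSE
K03778	ldhA	D-lactate dehydrogenase	1.1.1.28	TRUE
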