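pdb_id	protein_name	organism	n_residues	method	pct_310	pct_alpha	pct_beta	ph	resolution_A	r_work	r_free	ff_coverage	paired_id	nmr_data	note
4LFQ	potassium channel toxin L-ShK	Stichodactyla helianthus	35	xray	9	34	–	7.0	1.1	0.13	0.16	all	–	–	–
2NLS	human beta-defensin-1, mutant Q24A	Homo sapiens	36	xray	–	19	31	7.5	1.0	0.11	0.12	54A7/8	–	–	–
3E7U	plectasin	Pseudoplectania nigrella	40	xray	3	23	25	7.5	1.4	0.16	0.18	all	–	–	–
2GKT	turkey ovomucoid third domain	Meleagris gallopavo	51	xray	–	20	16	7.5	1.2	0.13	0.15	all	–	–	–
3CA7	protein Spitz	Drosophila melanogaster	52	xray	–	12	38	6.5	1.5	0.2	0.24	54A7/8	–	–	–
1PGB	protein G, B1 domain	Streptococcus sp. gx7805	56	xray	–	25	43	4.5	1.9	0.20	–	all	2GB1	–	–
1ZLM	osteoclast stimulating factor 1	Homo sapiens	58	xray	5	–	48	7.5	1.1	0.16	0.21	all	–	–	–
1SHG	alpha-spectrin	Gallus gallus	62	xray	5	–	49	4.0	1.8	0.2	0.28	all	1AEY	–	–
1UCS	antifreeze peptide RD1	Lycodichthys dearborni	64	xray	14	6	25	7.5	0.6	0.14	0.15	all	–	–	–
1ZVG	alpha-like neurotoxin BmK-I	Mesobuthus martensii	66	xray	2	15	30	6.0	1.2	0.16	0.16	all	–	–	–
1YU5	villin headpiece	Gallus gallus	67	xray	10	45	–	7.0	1.4	0.19	0.22	all	1QQV	–	–
1MJC	major cold shock protein	Escherichia coli	69	xray	4	–	46	7.5	2.0	0.19	–	all	–	–	–
1UBI	ubiquitin	Homo sapiens	76	xray	8	16	33	5.6	1.8	0.17	–	all	1D3Z	–	–
2J8B	human CD59 glycoprotein	Homo sapiens	79	xray	8	10	32	7.5	1.1	0.17	0.2	54A7/8	–	–	–
2PNE	glycine-rich antifreeze protein	Hypogastrura harveyi	81	xray	–	–	–	6.5	1.0	0.14	0.16	all	–	–	polyproline II spiral only, not detected by DSSP
1ULR	putative acylphosphatase	Thermus thermophilus	88	xray	1	28	38	7.0	1.3	0.19	0.22	all	–	–	pH not reported, set to 7.0
1A19	barstar, mutant C82A	Bacillus amyloliquefaciens	90	xray	2	44	17	6.5	2.8	0.2	0.29	54A7/8	1BTA	–	–
4RWU	protein Sis1	Saccharomyces cerevisiae s288c	92	xray	–	62	–	7.0	1.2	0.12	0.15	54A7/8	–	–	–
1T2I	ribonuclease Sa	Streptomyces aureofaciens	96	xray	3	11	22	7.2	1.1	0.13	0.17	all	–	–	–
2YXF	beta-2-microglobulin	Homo sapiens	100	xray	–	–	49	7.0	1.1	0.18	0.2	54A7/8	–	–	–
2CWR	chitin binding domain of chitinase	Pyrococcus furiosus	103	xray	–	–	62	6.5	1.7	0.19	0.23	all	2CZN	–	–
2RB8	tenascin	Homo sapiens	104	xray	–	–	48	7.5	1.4	0.17	0.2	54A7/8	–	–	–
1EW4	CyaY	Escherichia coli	106	xray	–	31	32	5.1	1.4	0.19	0.21	all	–	–	–
2PPO	FK506 binding protein-12 (FKBP12), mutant E60A	Homo sapiens	107	xray	4	7	37	7.0	1.3	0.13	0.18	all	–	–	–
2PND	murine CRIg	Mus musculus	119	xray	5	–	51	7.5	1.0	0.12	0.14	54A7/8	–	–	–
1FAZ	phospholipase A2	Streptomyces violaceoruber	122	xray	10	57	–	6.0	1.4	0.19	0.23	all	1IT5	–	–
1TVQ	chicken liver basic fatty acid binding protein	Gallus gallus	125	xray	–	11	58	7.5	2.0	0.23	0.27	all	1MVG	–	–
1AKI	lysozyme	Gallus gallus	129	xray	13	30	11	4.5	1.5	0.21	–	all	1E8L	–	–
1UXZ	cellulase B	Cellvibrio mixtus	131	xray	2	–	56	7.0	1.4	0.16	0.18	all	–	–	–
1QK8	tryparedoxin-I	Crithidia fasciculata	146	xray	8	27	22	7.5	1.4	0.19	0.22	all	–	–	–
1NG6	hypothetical protein yqeY	Bacillus subtilis	148	xray	4	74	–	5.5	1.4	0.21	0.25	all	–	–	–
2WLW	TRIM5-CypA	Macaca mulatta	165	xray	3	12	32	7.4	1.5	0.16	0.19	54A7/8	–	–	–
3EYE	PTS system N-acetylgalactosamine-specific IIB component 1	Escherichia coli O157:H7	168	xray	5	35	24	7.0	1.4	0.19	0.22	54A7/8	–	–	–
1FL0	endothelial monocyte-activating polypeptide II	Homo sapiens	171	xray	7	2	37	7.5	1.5	0.22	0.22	all	–	–	–
1AMM	gamma-crystallin B	Bos taurus	174	xray	6	3	40	6.8	1.2	0.18	–	all	–	–	–
1TUA	hypothetical protein APE0754	Aeropyrum pernix	191	xray	7	53	18	7.0	1.5	0.21	0.23	all	–	–	pH not reported, set to 7.0
2PTH	peptidyl-tRNA hydrolase	Escherichia coli	193	xray	7	38	21	7.5	1.2	0.2	0.21	54A7/8	–	–	–
3WP5	xylanase CDBFV, mutant E109A	Neocallimastix patriciarum	227	xray	2	8	54	6.5	1.3	0.15	0.18	all	–	–	–
4MHP	putative glutaminyl cyclase	Ixodes scapularis	326	xray	6	33	17	7.5	1.1	0.17	0.19	all	–	–	–
2OVN	GCN4 trigger peptide (p16-31)	Saccharomyces cerevisiae	17	nmr	–	76	–	7.5	–	–	–	all	–	NOE+Jval	–
2GB1	protein G, B1 domain	Streptococcus sp. group G	56	nmr	1	18	44	7.0	–	–	–	all	1PGB	–	pH not reported, set to 7.0
1AEY	alpha-spectrin	Gallus gallus	62	nmr	5	–	48	3.5	–	–	–	all	1SHG	–	–
3CI2	chymotrypsin inhibitor 2 (CI-2)	Hordeum vulgare	66	nmr	–	17	17	4.2	–	–	–	all	–	NOE+Jval	–
1QQV	villin headpiece	Gallus gallus	67	nmr	7	37	–	7.0	–	–	–	all	1YU5	NOE+Jval	–
1AFI	mercury binding protein (MerP)	Shigella flexneri	72	nmr	–	29	28	6.5	–	–	–	all	–	NOE	–
1D3Z	ubiquitin	Homo sapiens	76	nmr	8	16	33	6.5	–	–	–	all	1UBI	NOE+Jval+RDC	–
2AF8	actinorhodin polyketide synthase acyl carrier protein	Streptomyces coelicolor	86	nmr	–	50	–	4.9	–	–	–	54A7/8	–	–	–
1BTA	barstar	Bacillus amyloliquefaciens	89	nmr	3	42	18	6.7	–	–	–	all	1A19	Jval	–
2CZN	chitin binding domain of chitinase	Pyrococcus furiosus	103	nmr	–	–	51	5.6	–	–	–	all	2CWR	NOE	–
1IT5	phospholipase A2	Streptomyces violaceoruber	122	nmr	11	57	–	7.6	–	–	–	all	1FAZ	–	–
1MVG	chicken liver basic fatty acid binding protein	Gallus gallus	125	nmr	1	12	59	5.6	–	–	–	all	1TVQ	NOE+Jval	–
1E8L	lysozyme	Gallus gallus	129	nmr	2	29	6	3.8	–	–	–	all	1AKI	NOE+Jval	–
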