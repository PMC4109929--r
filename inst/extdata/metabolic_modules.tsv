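module_id	symbols	min_fraction	single_gene	notes
mxaFJGI	mxaF,mxaJ,mxaG,mxaI	1.0	FALSE	classic two-subunit methanol dehydrogenase operon
xoxF	xoxF	1.0	TRUE	lanthanide-associated methanol dehydrogenase copies
mxaRSACKL	mxaR,mxaS,mxaA,mxaC,mxaK,mxaL,mxaD	0.5	FALSE	MDH accessory gene cluster copies; mxaD single-copy
pqqA	pqqA	1.0	TRUE	PQQ precursor peptide copies
pqqBCDEFG	pqqB,pqqC,pqqD,pqqE,pqqF,pqqG	0.8	FALSE	PQQ biosynthesis operon
mau	mauF,mauB,mauE,mauD,mauA,mauG,mauL,mauM,mauN	0.8	FALSE	methylamine dehydrogenase gene cluster
nmg	mgdA,mgdB,mgdC,mgdD,gma,mgsA,mgsB,mgsC	0.75	FALSE	N-methylglutamate pathway
fae	fae	1.0	TRUE	formaldehyde-activating enzyme copies
fae2	fae2	1.0	TRUE	Fae2 homolog
fae3	fae3	1.0	TRUE	Fae3 homolog
h4mpt	fhcA,fhcB,fhcC,fhcD,mptG,mtdB,mch	0.8	FALSE	tetrahydromethanopterin pathway core genes
fdh1	fdh1A,fdh1B,fdh1C,fdh1D,fdh1E	0.8	FALSE	NAD-dependent formate dehydrogenase
fdh4	fdh4A,fdh4B	1.0	FALSE	formate dehydrogenase 4
rump	hps1,hps2,hpi,tal,pgi,zwf,pgl,edd,eda,tkt,rpe,ppi	0.75	FALSE	assimilatory RuMP cycle gene set
gndA	gndA	1.0	TRUE	NAD-dependent 6-phosphogluconate dehydrogenase
gndB	gndB	1.0	TRUE	NADP-dependent 6-phosphogluconate dehydrogenase
mcc	prpC,prpB,prpD,maoC,prpE,fum,can	0.7	FALSE	methylcitric acid cycle cluster
nap	nap	1.0	TRUE	periplasmic assimilatory nitrate reductase copies
narABC	narA,narB,narC	1.0	FALSE	respiratory nitrate reductase
nirBD	nirB,nirD	1.0	FALSE	NADP-linked nitrite reductase cluster copies
nirK	nirK	1.0	TRUE	copper nitrite reductase
norBD	norB,norD	0.5	FALSE	nitric oxide reductase; NorB alone counts (footnoted case)
nosZ	nosZ	1.0	TRUE	nitrous oxide reductase
gs_gogat	glnA,gltB,gltD	0.7	FALSE	GS/GOGAT ammonia assimilation
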