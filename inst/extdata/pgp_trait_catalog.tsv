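# Plant-growth-promoting trait gene catalog. One row per trait gene:
# comma-separated gene symbols (matched exactly after lowercasing and
# hyphen stripping) and semicolon-separated case-insensitive product
# patterns. Direct mechanisms: phosphate solubilization and regulation,
# tryptophan/IAA pathway, auxin signaling, ACC deaminase. Indirect
# mechanisms: lytic enzymes and antibiotic biosynthesis.
trait	symbols	patterns
ppx-gppA	ppx-gppA,ppx,gppA	exopolyphosphatase;guanosine.*pentaphosphate.*phosphohydrolase;inorganic polyphosphate
pstS	pstS	phosphate[- ]binding protein;phosphate ABC transporter.*substrate
senX3	senX3	sensor histidine kinase SenX3;histidine kinase.*phosphate regulon
trpA	trpA	tryptophan synthase.*alpha
trpB	trpB	tryptophan synthase.*beta
trpD	trpD	anthranilate phosphoribosyl ?transferase
trpE	trpE	anthranilate synthase
trpF	trpF	phosphoribosylanthranilate isomerase
pdxI	pdxI,pdxl	pyridoxine 4-dehydrogenase
aad	aad	aryl-alcohol dehydrogenase
acc	acc,acdS	1-aminocyclopropane-1-carboxylate deaminase;ACC deaminase
fabG	fabG	3-oxoacyl-\[?acyl-carrier-protein\]? reductase
bacC2	bacC2,bacC	bacitracin synth
hdhA	hdhA	7-alpha-hydroxysteroid dehydrogenase
auaJ	auaJ	epoxidase LasC;lasalocid.*epoxidase
tcmO	tcmO	tetracenomycin.*O-methyltransferase;8-O-methyl ?transferase
chitinase	chiA,chiB,chiC	chitinase
glucoamylase	glaA	glucoamylase
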