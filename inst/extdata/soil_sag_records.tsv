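# Marker-gene completeness and assembly statistics of single-cell
# amplified genomes sorted from a soil cell extract, grouped by sorting
# criterion: cells carrying the C-D band after heavy-water incubation
# (cd_peak) and cells carrying carotenoid resonance bands (carotenoid).
sample_id	group	genus	completeness_pct	genome_kbp	gc_pct
SR5	cd_peak	Corynebacterium	89.05	3003.41	60.12
SR6	cd_peak	Clostridium	22.25	1272.90	30.05
SR9	cd_peak	Moraxella	92.62	4772.96	43.21
BSR2	cd_peak	Pantoea	46.90	2397.74	54.60
BSR3	cd_peak	Pseudomonas	11.68	863.39	62.17
BSR5	cd_peak	Pantoea	23.43	1303.76	55.61
BSR11	cd_peak	Moraxella	90.23	2465.43	43.60
CRG1	carotenoid	Pantoea	58.66	3419.94	52.55
CRG2	carotenoid	Legionella	34.99	960.72	39.05
CRG4	carotenoid	Legionella	48.39	1202.08	37.93
CRG5	carotenoid	Legionella	12.23	143.52	38.89
CRG6	carotenoid	Massilia	19.44	605.58	62.84
CRG7	carotenoid	Pseudomonas	20.85	1698.06	58.72
CRG11	carotenoid	Pedobacter	13.01	43.11	41.25
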