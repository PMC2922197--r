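rank	parent	taxon	n_enzymes	n_tsps	n_hits	factor
kingdom	NA	Archaea	543	408	1807	3.33
kingdom	NA	Eukaryota	259	150	260	1.00
kingdom	NA	Bacteria	7752	8310	98556	12.71
phylum	Bacteria	Proteobacteria	4341	3768	34376	7.92
phylum	Bacteria	Firmicutes	1561	1130	7457	4.78
phylum	Bacteria	Cyanobacteria	328	175	541	1.65
phylum	Bacteria	Actinobacteria	494	392	1874	3.79
phylum	Bacteria	Tenericutes	193	25	72	0.37
phylum	Bacteria	Bacteroidetes	132	103	223	1.69
phylum	Bacteria	Spirochaetes	185	71	173	0.94
phylum	Bacteria	Thermotogae	81	9	22	0.27
phylum	Bacteria	Chlamydiae	114	140	383	3.36
phylum	Bacteria	Chlorobi	90	31	79	0.88
phylum	Archaea	Crenarchaeota	165	53	158	0.96
phylum	Archaea	Euryarchaeota	359	281	932	2.60
class	Proteobacteria	Gammaproteobacteria	2372	1624	13622	5.74
class	Proteobacteria	Alphaproteobacteria	870	675	3806	4.37
class	Proteobacteria	Betaproteobacteria	638	394	1950	3.06
class	Proteobacteria	Epsilonproteobacteria	223	178	430	1.93
class	Proteobacteria	Deltaproteobacteria	229	9	19	0.08
class	Firmicutes	Bacillales	614	327	1811	2.95
class	Firmicutes	Clostridia	374	142	567	1.52
class	Firmicutes	Lactobacillales	573	387	2543	4.44
class	Cyanobacteria	Chroococcales	114	64	184	1.61
class	Bacteroidetes	Bacteroidia	85	67	138	1.62
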