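species	prefix	n_records	n_in_species_specific_clades	n_species_specific_clades	average_root_tip
Nematostella vectensis	Nv	127	66	22	1.010
Drosophila melanogaster	Dm	102	25	12	1.052
Trichoplax adhaerens	Ta	35	0	0	1.162
Amphimedon queenslandica	Aq	31	7	2	1.286
Homo sapiens	Hs	256	197	74	1.293
Mnemiopsis leidyi	Ml	76	45	14	1.344
Caenorhabditis elegans	Ce	113	34	11	1.480
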