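species	total_size_bp	gc_percent	gc_skew	at_skew	n_pcg	n_trna	n_rrna	n_introns	exonic_bp	intergenic_bp	intronic_bp
Lysurus mokusin	99150	24.6	0.0929	0.0215	15	24	2	24	14085	38138	40097
Phallus hadriani	93486	24.5	0.1	0.0225	15	25	2	14	14802	37942	35965
Phallus rugulosus	61654	25.1	0.0955	0.0171	15	25	2	16	15495	15579	24071
Phallus indusiatus	83590	24.5	0.0891	0.0317	15	24	2	30	15861	14442	46803
Phallus rigidiindusiatus	41465	24.1	0.094	0.0002	15	25	2	5	15864	12819	6231
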