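species	strain	total_size_bp
Lysurus mokusin	1	99150
Lysurus mokusin	2	101135
Phallus indusiatus	1	83590
Phallus indusiatus	2	89139
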