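taxon	role	GenBank	Soil
Actinobacteria	analysis	157719	20870
OtherBacteria	analysis	1181150	79224
Archaea	archaea	180441	0
uncultured	uncultured	2143037	0
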