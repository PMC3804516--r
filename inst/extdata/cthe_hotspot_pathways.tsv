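group_id	locus_tag
amino_acid_production	Cthe_0948
amino_acid_production	Cthe_0949
amino_acid_production	Cthe_1766
amino_acid_production	Cthe_1866
amino_acid_production	Cthe_2529
rex_acetate_formation	Cthe_0422
rex_acetate_formation	Cthe_0423
rex_acetate_formation	Cthe_1028
rex_acetate_formation	Cthe_1029
homocysteine_biosynthesis	Cthe_1569
homocysteine_biosynthesis	Cthe_1842
glycoside_hydrolases	Cthe_1256
glycoside_hydrolases	Cthe_2119
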