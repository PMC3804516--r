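group_id	locus_tag
atp_synthase_unit	Cthe_2602
atp_synthase_unit	Cthe_2603
atp_synthase_unit	Cthe_2604
atp_synthase_unit	Cthe_2605
atp_synthase_unit	Cthe_2606
atp_synthase_unit	Cthe_2607
atp_synthase_unit	Cthe_2608
atp_synthase_unit	Cthe_2609
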