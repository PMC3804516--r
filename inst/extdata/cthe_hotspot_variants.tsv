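variant_id	locus_tag	region	core
v_Cthe_0948_1	Cthe_0948	CDS	TRUE
v_Cthe_0949_1	Cthe_0949	CDS	TRUE
v_Cthe_1766_1	Cthe_1766	CDS	TRUE
v_Cthe_1866_1	Cthe_1866	CDS	TRUE
v_Cthe_2529_1	Cthe_2529	CDS	FALSE
v_Cthe_2602_1	Cthe_2602	NC	TRUE
v_Cthe_2602_2	Cthe_2602	NC	FALSE
v_Cthe_2603_1	Cthe_2603	CDS	FALSE
v_Cthe_2603_2	Cthe_2603	CDS	FALSE
v_Cthe_2607_1	Cthe_2607	CDS	FALSE
v_Cthe_0422_1	Cthe_0422	NC	TRUE
v_Cthe_0422_2	Cthe_0422	CDS	FALSE
v_Cthe_1028_1	Cthe_1028	CDS	FALSE
v_Cthe_1029_1	Cthe_1029	CDS	FALSE
v_Cthe_1569_1	Cthe_1569	CDS	TRUE
v_Cthe_1842_1	Cthe_1842	CDS	TRUE
v_Cthe_1202_1	Cthe_1202	NC	TRUE
v_Cthe_1202_2	Cthe_1202	CDS	TRUE
v_Cthe_1020_1	Cthe_1020	CDS	TRUE
v_Cthe_1020_2	Cthe_1020	CDS	FALSE
v_Cthe_3087_1	Cthe_3087	CDS	TRUE
v_Cthe_3087_2	Cthe_3087	CDS	FALSE
v_Cthe_1256_1	Cthe_1256	CDS	TRUE
v_Cthe_2119_1	Cthe_2119	CDS	TRUE
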