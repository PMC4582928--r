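name	contig	start	end	flags
color_locus_1Mb	chr_D_synthetic	1	1000000	is_color_locus
functional_65kb	chr_D_synthetic	467501	532500	is_functional_65kb
unlinked_1	chr_U1_synthetic	1	150000	is_unlinked
unlinked_2	chr_U2_synthetic	1	120000	is_unlinked
unlinked_3	chr_U3_synthetic	1	80000	is_unlinked
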