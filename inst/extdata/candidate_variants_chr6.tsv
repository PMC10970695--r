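gene_id	chrom	pos	p1	p2	reported_category
Scaffold_9372_HRSCAF_11447.163	Chr6	836049	G	GT	Intron
Scaffold_9372_HRSCAF_11447.163	Chr6	838193	A	AT	Intron
Scaffold_9372_HRSCAF_11447.163	Chr6	839519	C	CAAAAGAAAAG	Downstream
Scaffold_9372_HRSCAF_11447.163	Chr6	839654	AT	A	Downstream
Scaffold_9372_HRSCAF_11447.164	Chr6	842357	TCCG	T	Codon_insertion
Scaffold_9372_HRSCAF_11447.164	Chr6	843363	AAAG	A	Intron
Scaffold_9372_HRSCAF_11447.165	Chr6	848154	A	ACAGAG	Upstream
Scaffold_9372_HRSCAF_11447.165	Chr6	848319	T	TA	Upstream
Scaffold_9372_HRSCAF_11447.165	Chr6	849984	AATT	A	Downstream
Scaffold_9372_HRSCAF_11447.166	Chr6	855253	T	TA	Upstream
Scaffold_9372_HRSCAF_11447.166	Chr6	855365	A	ATTTT	Upstream
Scaffold_9372_HRSCAF_11447.168	Chr6	873299	G	GT	Downstream
Scaffold_9372_HRSCAF_11447.168	Chr6	873465	T	TA	Downstream
Scaffold_9372_HRSCAF_11447.168	Chr6	873655	T	TATTATC	Downstream
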