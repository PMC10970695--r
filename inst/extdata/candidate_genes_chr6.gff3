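##gff-version 3
# Candidate-gene models within the mapped trichome QTL interval on Chr6
# of black gram (Vigna mungo). Gene spans and annotations as published.
# Exon spans for Scaffold_9372_HRSCAF_11447.164 are SYNTHETIC: the
# published record gives only the gene span, so two placeholder exons
# were invented to exercise coding-region classification.
Chr6	binQTL	gene	834818	839129	.	+	.	ID=Scaffold_9372_HRSCAF_11447.163;Note=stAR-related lipid transfer protein 7
Chr6	binQTL	gene	842193	847000	.	+	.	ID=Scaffold_9372_HRSCAF_11447.164;Note=RNA polymerase-associated protein Rtf1
Chr6	binQTL	exon	842193	842600	.	+	.	ID=Scaffold_9372_HRSCAF_11447.164.exon1;Parent=Scaffold_9372_HRSCAF_11447.164
Chr6	binQTL	exon	843600	847000	.	+	.	ID=Scaffold_9372_HRSCAF_11447.164.exon2;Parent=Scaffold_9372_HRSCAF_11447.164
Chr6	binQTL	gene	848491	849285	.	+	.	ID=Scaffold_9372_HRSCAF_11447.165;Note=CDI cadmium 2+ induced
Chr6	binQTL	gene	858351	865191	.	+	.	ID=Scaffold_9372_HRSCAF_11447.166;Note=Bromodomain adjacent to zinc-finger domain protein 1A
Chr6	binQTL	gene	867211	869064	.	+	.	ID=Scaffold_9372_HRSCAF_11447.167;Note=Histone demethylase JARID1
Chr6	binQTL	gene	870460	872091	.	+	.	ID=Scaffold_9372_HRSCAF_11447.168;Note=RGF1 INDUCIBLE TRANSCRIPTION FACTOR 1
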