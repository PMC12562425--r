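# Known alternative junctions of the CDH1 synthetic fixture model.
# Spans are 1-based inclusive gap coordinates (first/last intronic base).
# The two skip junctions are specific to the Ensembl NMD transcripts the
# exon-11 and exon-6 skips correspond to; the two intron-2 junctions mark
# the end of exon 1 of reported alternative transcripts (synthetic
# placeholder labels).
chrom	g_start	g_end	label
chr16	68849679	68856499	ENST00000566612.1
chr16	68844501	68846345	ENST00000561751.1
chr16	68781358	68836615	CDH1-alt-exon1-A
chr16	68795358	68836615	CDH1-alt-exon1-B
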