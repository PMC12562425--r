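# gene: CDH1
# transcript_id: NM_004360.3-like (synthetic genomic coordinates)
# chrom: chr16
# strand: +
# cds_start: 1
# cds_end: 2649
# note: cDNA exon boundaries follow published CDH1 c. splice positions;
# note: genomic positions are synthetic (intron 2 = 63258 bp; exon 4-11
# note: duplication breakpoints 68841756/68855314 fall in introns 3/11)
exon_index	chrom	strand	g_start	g_end
1	chr16	+	68771195	68771242
2	chr16	+	68773243	68773357
3	chr16	+	68836616	68836839
4	chr16	+	68843001	68843144
5	chr16	+	68844345	68844500
6	chr16	+	68845301	68845445
7	chr16	+	68846346	68846521
8	chr16	+	68847522	68847650
9	chr16	+	68848351	68848533
10	chr16	+	68849434	68849678
11	chr16	+	68850779	68850924
12	chr16	+	68856500	68856724
13	chr16	+	68857725	68857952
14	chr16	+	68860453	68860583
15	chr16	+	68861384	68861527
16	chr16	+	68862428	68862637
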