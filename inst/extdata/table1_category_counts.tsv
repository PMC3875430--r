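# Published per-category read counts of the three common-wild-rice
# small-RNA libraries (reporting fixture for the category-percentage
# arithmetic). clean_reads is the genome-matched clean total.
category	CWR-V1	CWR-V2	CWR-F2
clean_reads	20156098	21531511	20995942
exon_antisense	112669	216290	207313
exon_sense	533039	389764	537402
intron_antisense	108493	199531	147424
intron_sense	151224	267035	184186
miRNA	3448185	4265048	2833527
rRNA	9501946	7094006	10111526
repeat	1964625	2624071	1681420
snRNA	18076	16987	19862
snoRNA	7471	11091	10080
tRNA	1480266	1928031	1705003
unann	2830104	4519657	3558199
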