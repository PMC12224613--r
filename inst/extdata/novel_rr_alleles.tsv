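locus	chrom_class	motif_len	copy_count	designation	motif	count	frequency
D11S2368	autosomal	4	1	18	[TATC]3 [TGTC]5 [TATC]10	1	0.005
D11S2368	autosomal	4	1	19	CATC [TATC]2 [TGTC]2 [TATC]14	1	0.005
D11S2368	autosomal	4	1	21	[TATC]3 [TGTC]3 [TATC]15	2	0.01
D11S4463	autosomal	4	1	12	[TGTC]1 [TGTC]1 [TATC]10	1	0.005
D11S4463	autosomal	4	1	13	[TGTC]1 [TGTC]1 [TATC]11	2	0.01
D11S4463	autosomal	4	1	14	[TGTC]1 [TGTC]1 [TATC]12	1	0.005
D13S325	autosomal	4	1	17	[TCTA]7 TCA [TCTA]10	2	0.01
D13S325	autosomal	4	1	18	[TCTA]7 TCA [TCTA]11	2	0.01
D13S325	autosomal	4	1	18	[TCTA]9 TCA [TCTA]9	4	0.02
D13S325	autosomal	4	1	19	[TCTA]10 TCA [TCTA]9	6	0.03
D13S325	autosomal	4	1	19	[TCTA]11 TCA [TCTA]8	1	0.005
D13S325	autosomal	4	1	19	[TCTA]8 TCA [TCTA]11	1	0.005
D13S325	autosomal	4	1	20	[TCTA]8 TCTG [TCTA]1 TCA [TCTA]10	1	0.005
D13S325	autosomal	4	1	22	[TCTA]10 TCA [TCCA]1 [TCTA]11	1	0.005
D13S325	autosomal	4	1	23	[TCTA]4 [TATA]1 [TCTA]9 TCA [TCTA]9	1	0.005
D13S325	autosomal	4	1	24	[TCTA]11 TCA [TCTA]13	1	0.005
D13S325	autosomal	4	1	24	[TCTA]12 TCA [TCTA]12	1	0.005
D13S325	autosomal	4	1	24	[TCTA]13 TCA [TCTA]11	2	0.01
D13S325	autosomal	4	1	25	[TCTA]14 TCA [TCTA]11	1	0.005
D8S1179	autosomal	4	1	19	[TCTA]2 [TCTG]1 [TCTA]16	1	0.005
D15S659	autosomal	4	1	13	[TATC]7 [TACC]1 [TATC]5	1	0.005
D15S659	autosomal	4	1	14	[TATC]8 [TACC]1 [TATC]5	1	0.005
D15S659	autosomal	4	1	16	[TATC]16	1	0.005
D1S1677	autosomal	4	1	14	[TTCC]1 TTCT [TTCC]12	1	0.005
D20S470	autosomal	4	1	8	[AGGA]8	1	0.005
D20S482	autosomal	4	1	12	[AGAT]8 AGTT [AGAT]3	1	0.005
D17S1290	autosomal	4	1	13	[AGAT]4 GATG [ATAG]15	1	0.005
D17S1290	autosomal	4	1	15.2	[AGAT]4 GATG [ATAGATAT]3 [ATAG]8 AT [ATAG]3	1	0.005
D18S51	autosomal	4	1	17.1	[AGAA]5 A [AGAA]12	1	0.005
D18S853	autosomal	3	1	11	[ATA]10 AAA	1	0.005
D14S1434	autosomal	4	1	13.3	[CTGT]3 [CTAT]2 CAT [CTAT]8	1	0.005
D7S3048	autosomal	4	1	16	[TATC]9 [TACC]7	1	0.005
D7S3048	autosomal	4	1	18	[TATC]12 [TACC]6	1	0.005
D7S3048	autosomal	4	1	20	[TATC]13 [TACC]7	2	0.01
D7S3048	autosomal	4	1	21	[TATC]11 [TACC]8 [CACC]2	1	0.005
D7S3048	autosomal	4	1	21	[TATC]12 [TACC]7 [CACC]2	4	0.02
D7S3048	autosomal	4	1	21	[TATC]10 [TACC]8 [CACC]3	1	0.005
D7S3048	autosomal	4	1	22	[TATC]14 [TACC]8	1	0.005
D7S3048	autosomal	4	1	23	[TATC]12 [TACC]6 [CACC]1 [TACC]2 [CACC]2	1	0.005
D7S3048	autosomal	4	1	25	[TATC]14 [TACC]9 [CACC]2	1	0.005
D7S3048	autosomal	4	1	26	[TATC]15 [TACC]9 [CACC]2	1	0.005
D3S1744	autosomal	4	1	16	[ATAG]2 ATG [ATAG]13 AG [ATAG]1	1	0.005
D8S1132	autosomal	4	1	14.1	[TCTA]13 TCTG [TCTA]1	3	0.015
D8S1132	autosomal	4	1	19	[TCTA]8 TCA [TCTA]11	1	0.005
D8S1132	autosomal	4	1	19	[TCTA]7 TCA [TCTA]10 [TCTG]1 [TCTA]1	1	0.005
D8S1132	autosomal	4	1	20	[TCTA]10 TCA [TCTA]8 TCTG [TCTA]1	1	0.005
D8S1132	autosomal	4	1	20	[TCTA]9 TCA [TCTA]9 TCTG [TCTA]1	1	0.005
D8S1132	autosomal	4	1	21.3	[TCTA]8 TCA [TCTA]3 TCA [TCTA]8 [TCTG]1 [TCTA]1	1	0.005
D21S1270	autosomal	4	1	10.3	[ATAG]3 ATG [ATAG]1 ATG [ATAG]1 ATG [ATAG]5	1	0.005
D7S1517	autosomal	4	1	15	[CTTT]2 [GTTT]1 [CTTT]2 [GTTT]3 [CTTT]7	2	0.01
D7S1517	autosomal	4	1	17	[CTTT]2 [GTTT]1 [CTTT]2 [GTTT]3 [CTTT]9	1	0.005
D7S1517	autosomal	4	1	19	[CTTT]2 [GTTT]1 [CTTT]2 [GTTT]4 [CTTT]10	1	0.005
D7S1517	autosomal	4	1	20	[CTTT]2 [GTTT]1 [CTTT]2 [GTTT]2 [CTTT]13	4	0.02
D7S1517	autosomal	4	1	23	[CTTT]2 [GTTT]1 [CTTT]2 [GTTT]5 [CTTT]13	3	0.015
D7S1517	autosomal	4	1	25	[CTTT]2 [GTTT]1 [CTTT]2 [GTTT]5 [CTTT]15	1	0.005
D7S1517	autosomal	4	1	26	[CTTT]2 [GTTT]1 [CTTT]2 [GTTT]1 [CTTT]2 [GTTT]1 [CTTC]1 [CTTT]1 [GTTT]1 [CTTT]2 [GTTT]1 [CTTT]2 [GTTT]1 [CTTT]8	1	0.005
D7S1517	autosomal	4	1	27	[CTTT]2 [GTTT]1 [CTTT]2 [GTTT]1 [CTTT]2 [GTTT]1 [CTTC]1 [CTTT]1 [GTTT]1 [CTTT]2 [GTTT]1 [CTTT]2 [GTTT]1 [CTTT]9	4	0.02
DYS527a/b	Y	4	2	18	[GAAA]11 [GGAA]7	1	0.01
DYS527a/b	Y	4	2	22	[GAAA]14 [GGAA]8	1	0.01
DYS527a/b	Y	4	2	25	[GAAA]18 [GGAA]7	1	0.01
DYS458	Y	4	1	21	[GAAG]1 [GAAA]20	1	0.02
DYS518	Y	4	1	38	[AAAG]3 [GAAG]1 [AAAG]13 [GGAG]1 [AAAG]4 N6 [AAAG]12 N27 [AAGG]4	2	0.04
DYS518	Y	4	1	41	[AAAG]3 [GAAG]1 [AAAG]12 [GGAG]1 [AAAG]4 N6 [AAAG]16 N27 [AAGG]4	1	0.02
DYS518	Y	4	1	46	[AAAG]3 [GAAG]1 [AAAG]16 [GGAG]1 [AAAG]4 [GAAG]1 AG [AAAG]17 N27 [AAGG]4	1	0.02
DYS518	Y	4	1	47	[AAAG]3 [GAAG]1 [AAAG]18 [GGAG]1 [AAAG]4 [GAAG]1 AG [AAAG]16 N27 [AAGG]4	1	0.02
DYS645	Y	5	1	6	[TGTTT]6	1	0.02
DYS645	Y	5	1	11	[TGTTT]11	2	0.04
DYS710	Y	4	1	30.2	[AAAG]16 [AG]11 [AAAG]9	1	0.02
DYS710	Y	4	1	32	[AAAG]16 [AG]14 [AAAG]9	3	0.06
DYS710	Y	4	1	33	[AAAG]16 [AG]14 [AAAG]10	1	0.02
DYS710	Y	4	1	33.2	[AAAG]17 [AG]11 [AAAG]11	2	0.04
DYS710	Y	4	1	34	[AAAG]15 [AG]12 [AAAG]13	4	0.08
DYS710	Y	4	1	34	[AAAG]17 [AG]12 [AAAG]11	2	0.04
DYS710	Y	4	1	34.2	[AAAG]13 [AG]13 [AAAG]15	1	0.02
DYS710	Y	4	1	34.2	[AAAG]18 [AG]13 [AAAG]10	2	0.04
DYS710	Y	4	1	35	[AAAG]16 [AG]12 [AAAG]13	1	0.02
DYS710	Y	4	1	36.2	[AAAG]19 [AG]13 [AAAG]11	1	0.02
DYS710	Y	4	1	36.2	[AAAG]17 [AG]17 [AAAG]11	2	0.04
DYS710	Y	4	1	37	[AAAG]16 [AG]16 [AAAG]13	1	0.02
DYS710	Y	4	1	37	[AAAG]18 [AG]12 [AAAG]13	1	0.02
DYS710	Y	4	1	37.2	[AAAG]17 [AG]15 [AAAG]13	1	0.02
DYS710	Y	4	1	39	[AAAG]19 [AG]13 [AAAG]14	1	0.02
DYS710	Y	4	1	40	[AAAG]20 [AG]16 [AAAG]12	1	0.02
DYS710	Y	4	1	40.2	[AAAG]20 [AG]13 [AAAG]14	2	0.04
DYS710	Y	4	1	40.2	[AAAG]18 [AG]21 [AAAG]12	1	0.02
DYS710	Y	4	1	41	[AAAG]21 [AG]14 [AAAG]13	1	0.02
DYS710	Y	4	1	42	[AAAG]22 [AG]16 [AAAG]12	1	0.02
DYS587	Y	5	1	23	[ATACA]17 [GTACA]1 [ATACA]1 [GTACA]1 [ATACA]1 [GTACA]1 [ATACA]1	2	0.04
DYS626	Y	4	1	30	[AAAG]21 [AGAA]2 AGAG [GAAG]3 [AAAG]3	1	0.02
DYS644	Y	5	1	23.4	TTTTT [TTTTA]11 [TTTA]1 [TTTTA]11	1	0.02
DYF387S1a/b	Y	4	2	37.3	[AAAG]3 [GTAG]1 [GAAG]4 [AAAG]2 [GAAG]1 [AAAG]2 [GAAG]11 [AAAG]3 AAG [AAAG]10	2	0.02
DYF387S1a/b	Y	4	2	38	[AAAG]3 [GTAG]1 [GAAG]3 AAAA [AAAG]2 [GAAG]1 [AAAG]2 [GAAG]9 [AAAG]16	5	0.05
DYF387S1a/b	Y	4	2	39	[AAAG]3 [GTAG]1 [GAAG]3 GAAA [AAAG]2 [GAAG]1 [AAAG]2 [GAAG]9 [AAAG]17	3	0.03
DXS10074	X	4	1	20	[AGAA]16 [AGAG]1 [AGAA]3	1	0.005
DXS10135	X	4	1	20	[AAGA]3 G [AAAG]1 GA [AAGA]15 AAGC [AAAG]1	1	0.005
DXS10135	X	4	1	25	[AAGA]3 G [AAAG]1 GA [AAGA]19 AAGG [AAGA]1 [AAAG]1	1	0.005
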