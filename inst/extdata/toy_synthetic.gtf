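chr1	toy	exon	1001	1200	.	+	.	gene_id "TA"; transcript_id "TA.1";
chr1	toy	exon	2001	2150	.	+	.	gene_id "TA"; transcript_id "TA.1";
chr1	toy	exon	2901	3050	.	+	.	gene_id "TA"; transcript_id "TA.1";
chr1	toy	exon	3801	4000	.	+	.	gene_id "TA"; transcript_id "TA.1";
chr1	toy	exon	1001	1200	.	+	.	gene_id "TA"; transcript_id "TA.2";
chr1	toy	exon	2901	3050	.	+	.	gene_id "TA"; transcript_id "TA.2";
chr1	toy	exon	3801	4000	.	+	.	gene_id "TA"; transcript_id "TA.2";
chr1	toy	exon	5001	5200	.	+	.	gene_id "TB"; transcript_id "TB.1";
chr1	toy	exon	5901	5940	.	+	.	gene_id "TB"; transcript_id "TB.1";
chr1	toy	exon	6600	6749	.	+	.	gene_id "TB"; transcript_id "TB.1";
chr1	toy	exon	7450	7949	.	+	.	gene_id "TB"; transcript_id "TB.1";
chr1	toy	exon	8650	8849	.	+	.	gene_id "TB"; transcript_id "TB.1";
chr1	toy	exon	9001	9200	.	+	.	gene_id "TC"; transcript_id "TC.1";
chr1	toy	exon	9501	9650	.	+	.	gene_id "TC"; transcript_id "TC.1";
chr1	toy	exon	10401	10550	.	+	.	gene_id "TC"; transcript_id "TC.1";
chr1	toy	exon	11251	11450	.	+	.	gene_id "TC"; transcript_id "TC.1";
chr1	toy	exon	10001	10100	.	+	.	gene_id "TD"; transcript_id "TD.1";
chr1	toy	exon	10480	10600	.	+	.	gene_id "TD"; transcript_id "TD.1";
chr1	toy	exon	11900	11990	.	+	.	gene_id "TD"; transcript_id "TD.1";
chr1	toy	exon	13001	13200	.	+	.	gene_id "TE"; transcript_id "TE.1";
chr1	toy	exon	13901	14050	.	+	.	gene_id "TE"; transcript_id "TE.1";
chr1	toy	exon	14751	14900	.	+	.	gene_id "TE"; transcript_id "TE.1";
chr1	toy	exon	15601	15800	.	+	.	gene_id "TE"; transcript_id "TE.1";
chr1	toy	exon	13901	14050	.	+	.	gene_id "TE"; transcript_id "TE.2";
chr1	toy	exon	14751	14900	.	+	.	gene_id "TE"; transcript_id "TE.2";
chr1	toy	exon	15601	15800	.	+	.	gene_id "TE"; transcript_id "TE.2";
chr1	toy	exon	17001	17200	.	-	.	gene_id "TG"; transcript_id "TG.1";
chr1	toy	exon	17901	18050	.	-	.	gene_id "TG"; transcript_id "TG.1";
chr1	toy	exon	18751	18900	.	-	.	gene_id "TG"; transcript_id "TG.1";
chr1	toy	exon	19651	19850	.	-	.	gene_id "TG"; transcript_id "TG.1";
chrY	toy	exon	1001	1200	.	+	.	gene_id "TH"; transcript_id "TH.1";
chrY	toy	exon	1901	2050	.	+	.	gene_id "TH"; transcript_id "TH.1";
chrY	toy	exon	2751	2950	.	+	.	gene_id "TH"; transcript_id "TH.1";
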