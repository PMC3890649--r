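motif_id	matched	start	end	strand	disrupted
BIHD1OS	TGTCA	-1024	-1028	-	CKSV
BIHD1OS	TGTCA	-878	-874	+	.
BIHD1OS	TGTCA	-873	-869	+	.
BIHD1OS	TGTCA	-385	-389	-	.
BIHD1OS	TGTCA	-110	-106	+	.
GT1GMSCAM4	GAAAAA	-1678	-1673	+	.
GT1GMSCAM4	GAAAAA	-1069	-1064	+	.
GT1GMSCAM4	GAAAAA	-918	-923	-	.
GT1GMSCAM4	GAAAAA	-826	-821	+	C
GT1GMSCAM4	GAAAAA	-706	-701	+	SV
GT1GMSCAM4	GAAAAA	-505	-500	+	CSV
IBOXCORE	GATAA	-1834	-1838	-	.
IBOXCORE	GATAA	-1545	-1541	+	CKSV
IBOXCORE	GATAA	-1483	-1487	-	SV
IBOXCORE	GATAA	-1463	-1459	+	CKSV
IBOXCORE	GATAA	-1242	-1238	+	C
IBOXCORE	GATAA	-1121	-1117	+	.
IBOXCORE	GATAA	-1109	-1105	+	.
IBOXCORE	GATAA	-834	-830	+	.
IBOXCORE	GATAA	-537	-541	-	.
IBOXCORE	GATAA	-235	-239	-	CKSV
IBOXCORE	GATAA	-117	-121	-	K
MYB1AT	AAACCA	-1927	-1922	+	V
MYB1AT	AAACCA	-703	-698	+	SV
MYB1AT	TAACCA	-173	-168	+	.
MYB1AT	AAACCA	-15	-10	+	.
MYBST1	GGATA	-1556	-1552	+	CKSV
MYBST1	GGATA	-1299	-1303	-	.
MYBST1	GGATA	-1122	-1118	+	.
MYBST1	GGATA	-835	-831	+	.
MYBST1	GGATA	-116	-120	-	K
RAV1AAT	CAACA	-1834	-1830	+	.
RAV1AAT	CAACA	-1320	-1316	+	.
RAV1AAT	CAACA	-1242	-1246	-	.
RAV1AAT	CAACA	-981	-977	+	.
RAV1AAT	CAACA	-339	-335	+	.
RAV1AAT	CAACA	-281	-285	-	.
RAV1AAT	CAACA	-169	-165	+	.
SREATMSD	TTATCC	-1117	-1122	-	.
SREATMSD	TTATCC	-830	-835	-	.
SREATMSD	TTATCC	-121	-116	+	K
WUSATAg	TTAATGG	-15	-21	-	.
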