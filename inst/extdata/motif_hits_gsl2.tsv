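motif_id	matched	start	end	strand	disrupted
MYBPLANT	CACCTACC	-353	-346	+	.
RYREPEATVFLEB4	CATGCATG	-182	-175	+	.
SURE1STPAT21	AATAGAAAA	-101	-109	-	.
CPBCSPOR	TATTAG	-310	-315	-	.
GT1GMSCAM4	GAAAAA	-273	-278	-	CKSV
GT1GMSCAM4	GAAAAA	-193	-188	+	.
GT1GMSCAM4	GAAAAA	-143	-148	-	.
GT1GMSCAM4	GAAAAA	-105	-110	-	.
GT1GMSCAM4	GAAAAA	-21	-26	-	CV
MYBGAHV	TAACAAA	-467	-473	-	V
MYBST1	GGATA	-437	-433	+	.
NTBBF1ARROLB	ACTTTA	-374	-369	+	.
SREATMSD	TTATCC	-432	-437	-	.
WBOXHVISO1	TGACT	-13	-17	-	.
WUSATAg	TTAATGG	-224	-230	-	.
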