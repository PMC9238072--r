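##fileformat=VCFv4.2
##source=hearload
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene id">
##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence class">
##INFO=<ID=CADD,Number=1,Type=Float,Description="CADD score">
##INFO=<ID=SPLICEAI,Number=1,Type=Float,Description="SpliceAI delta score">
##INFO=<ID=SUTR,Number=1,Type=Float,Description="Sutr 5p UTR score">
##INFO=<ID=REMM,Number=1,Type=Float,Description="ReMM score">
##INFO=<ID=AF_GNOMAD_NFE,Number=1,Type=Float,Description="External allele frequency (gnomad_nfe)">
##INFO=<ID=AF_KG_EUR,Number=1,Type=Float,Description="External allele frequency (kg_eur)">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10
chr1	10500	v01	A	G	100	PASS	GENE=G_v01;CSQ=missense_variant;CADD=30;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	11000	v02	A	G	19	PASS	GENE=G_v02;CSQ=missense_variant;CADD=30;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	11500	v03	A	G	20	PASS	GENE=G_v03;CSQ=missense_variant;CADD=30;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	12000	v04	A	G	100	PASS	GENE=G_v04;CSQ=missense_variant;CADD=30;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:5:90	0/1:5:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	12500	v05	A	G	100	PASS	GENE=G_v05;CSQ=missense_variant;CADD=30;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:5:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	13000	v06	A	G	100	PASS	GENE=G_v06;CSQ=missense_variant;CADD=30;AF_GNOMAD_NFE=0.020	GT:DP:GQ	0/1:30:90	0/1:30:90	0/1:30:90	0/1:30:90	0/1:30:90	0/1:30:90	0/1:30:90	0/1:30:90	0/1:30:90	0/1:30:90
chr1	13500	v07	A	G	100	PASS	GENE=G_v07;CSQ=missense_variant;CADD=30;AF_GNOMAD_NFE=0.450	GT:DP:GQ	0/1:30:90	0/1:30:90	0/1:30:90	0/1:30:90	0/1:30:90	0/1:30:90	0/1:30:90	0/1:30:90	0/1:30:90	0/1:30:90
chr1	14000	v08	A	G	100	PASS	GENE=G_v08;CSQ=missense_variant;CADD=30;AF_GNOMAD_NFE=0.450	GT:DP:GQ	0/1:30:90	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	14500	v09	A	G	100	PASS	GENE=G_v09;CSQ=5_prime_UTR_variant;SUTR=1.5;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	15000	v10	A	G	100	PASS	GENE=G_v10;CSQ=5_prime_UTR_variant;SUTR=1.0;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	15500	v11	A	G	100	PASS	GENE=G_v11;CSQ=5_prime_UTR_variant;SUTR=0.5;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	16000	v12	A	G	100	PASS	GENE=G_v12;CSQ=3_prime_UTR_variant;CADD=40;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	16500	v13	A	G	100	PASS	GENE=G_v13;CSQ=regulatory_region_variant;REMM=0.96;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	17000	v14	A	G	100	PASS	GENE=G_v14;CSQ=regulatory_region_variant;REMM=0.95;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	17500	v15	A	G	100	PASS	GENE=G_v15;CSQ=intron_variant;REMM=0.20;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	18000	v16	A	G	100	PASS	GENE=G_v16;CSQ=splice_site_variant;CADD=5;SPLICEAI=0.6;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	18500	v17	A	G	100	PASS	GENE=G_v17;CSQ=splice_site_variant;CADD=5;SPLICEAI=0.5;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	19000	v18	A	G	100	PASS	GENE=G_v18;CSQ=missense_variant;CADD=25;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	19500	v19	A	G	100	PASS	GENE=G_v19;CSQ=mature_miRNA_variant;CADD=26;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	20000	v20	A	G	100	PASS	GENE=G_v20;CSQ=synonymous_variant;CADD=2;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	20500	v21	A	G	100	PASS	GENE=G_v21;CSQ=missense_variant;CADD=30;AF_GNOMAD_NFE=0.150	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	21000	v22	A	G	100	PASS	GENE=G_v22;CSQ=missense_variant;CADD=30;AF_GNOMAD_NFE=0.950;AF_KG_EUR=0.01	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	21500	v23	A	G	100	PASS	GENE=G_v23;CSQ=missense_variant;CADD=30	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	22000	v24	A	G	100	PASS	GENE=G_v24;CSQ=stop_gained;CADD=35;AF_GNOMAD_NFE=0.004	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	22500	v25	A	G	100	PASS	GENE=G_v25;CSQ=frameshift_variant;CADD=28;AF_GNOMAD_NFE=0.004	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	23000	v26	A	G	100	PASS	GENE=G_v26;CSQ=missense_variant&splice_site_variant;SPLICEAI=0.7;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	23500	v27	A	G	100	PASS	GENE=G_v27;CSQ=missense_variant;CADD=30;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:5	0/1:30:5	0/0:30:5	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	24000	v28	A	G	100	PASS	GENE=G_v28;CSQ=missense_variant;CADD=10;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	24500	v29	A	G	100	PASS	GENE=G_v29;CSQ=stop_lost;CADD=30;AF_GNOMAD_NFE=0.300	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
chr1	25000	v30	A	G	100	PASS	GENE=G_v30;CSQ=inframe_deletion;CADD=26;AF_GNOMAD_NFE=0.010	GT:DP:GQ	0/1:30:90	0/1:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90	0/0:30:90
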