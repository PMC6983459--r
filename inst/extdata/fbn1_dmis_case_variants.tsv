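subject_id	chrom	pos	ref	alt	gene	cdna_change	protein_change	exon	domain	af_gnomAD	af_gnomAD_EAS	cadd
XH1162	15	48902987	G	C	FBN1	c.284C>G	p.Ser95Trp	4	EGF-like #01	NA	NA	22.7
XH810	15	48807596	C	A	FBN1	c.1456G>T	p.Gly486Trp	12	EGF-like #04	NA	NA	24.6
XH152	15	48805763	G	T	FBN1	c.1571C>A	p.Thr524Lys	13	cbEGF-like #03	NA	NA	32
XH73	15	48787384	T	G	FBN1	c.2613A>C	p.Leu871Phe	22	Hybrid motif #02	0.00000406	0.000058	23.9
XH579	15	48787384	T	G	FBN1	c.2613A>C	p.Leu871Phe	22	Hybrid motif #02	0.00000406	0.000058	23.9
XH766	15	48779535	A	C	FBN1	c.3437T>G	p.Leu1146Arg	28	cbEGF-like #13	NA	NA	26.4
XH902	15	48729214	C	T	FBN1	c.6440G>A	p.Gly2147Asp	53	cbEGF-like #32	NA	NA	34
XH441	15	48722914	G	C	FBN1	c.6825C>G	p.Ile2275Met	56	cbEGF-like #35	NA	NA	20.6
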