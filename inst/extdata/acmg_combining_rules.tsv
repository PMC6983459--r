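class	rule	pvs	ps	pm	pp	ba	bs	bp
Pathogenic	P_ia	1	1	0	0	0	0	0
Pathogenic	P_ib	1	0	2	0	0	0	0
Pathogenic	P_ic	1	0	1	1	0	0	0
Pathogenic	P_id	1	0	0	2	0	0	0
Pathogenic	P_ii	0	2	0	0	0	0	0
Pathogenic	P_iiia	0	1	3	0	0	0	0
Pathogenic	P_iiib	0	1	2	2	0	0	0
Pathogenic	P_iiic	0	1	1	4	0	0	0
Likely pathogenic	LP_i	1	0	1	0	0	0	0
Likely pathogenic	LP_ii	0	1	1	0	0	0	0
Likely pathogenic	LP_iii	0	1	0	2	0	0	0
Likely pathogenic	LP_iv	0	0	3	0	0	0	0
Likely pathogenic	LP_v	0	0	2	2	0	0	0
Likely pathogenic	LP_vi	0	0	1	4	0	0	0
Benign	B_i	0	0	0	0	1	0	0
Benign	B_ii	0	0	0	0	0	2	0
Likely benign	LB_i	0	0	0	0	0	1	1
Likely benign	LB_ii	0	0	0	0	0	0	2
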