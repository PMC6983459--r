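start	end	name
60	100	EGF-like #01
460	500	EGF-like #04
505	545	cbEGF-like #03
855	925	Hybrid motif #02
1120	1160	cbEGF-like #13
2120	2165	cbEGF-like #32
2250	2290	cbEGF-like #35
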