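patient_id	chrom	pos	ref	alt	gene	transcript	hgvs_c	hgvs_p	coding_impact	zygosity
79	11	108300000	G	C	ATM	NM_000051.4	c.7570G>C	p.Ala2524Pro	missense	het
97	3	142562000	TACCATTGTCCTGAG	T	ATR	NM_001184.4	c.516_529del	p.Val173IlefsTer7	frameshift	het
40	13	32394600	A	G	BRCA2	NM_000059.4	c.9118-2A>G		missense	het
88	13	32380000	A	G	BRCA2	NM_000059.4	c.8177A>G	p.Tyr2726Cys	missense	het
53	22	28695000	AC	A	CHEK2	NM_001005735.2	c.1229delC	p.Thr410MetfsTer15	frameshift	het
66	22	28695000	AC	A	CHEK2	NM_001005735.2	c.1229delC	p.Thr410MetfsTer15	frameshift	het
78	22	28695000	AC	A	CHEK2	NM_001005735.2	c.1229delC	p.Thr410MetfsTer15	frameshift	het
91	22	28695000	AC	A	CHEK2	NM_001005735.2	c.1229delC	p.Thr410MetfsTer15	frameshift	het
113	22	28695000	AC	A	CHEK2	NM_001005735.2	c.1229delC	p.Thr410MetfsTer15	frameshift	het
113	7	124510000	T	A	POT1	NM_015450.3	c.458T>A	p.Leu153Ter	nonsense	het
82	7	124481000	G	C	POT1	NM_015450.3	c.1594G>C	p.Ala532Pro	missense	het
105	7	124503000	G	A	POT1	NM_015450.3	c.547-1G>A		splicing	het
35	16	23635000	CT	C	PALB2	NM_024675.4	c.1592delT	p.Leu531CysfsTer30	frameshift	het
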