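subset	n_individuals	variant_id	AC	AN	nHom
global	118477	7:124481000:G:C	6	188088	0
global	118477	22:28695000:AC:A	120	236954	0
finns	10816	22:28695000:AC:A	10	21632	0
global	118477	13:32380000:A:G	2	236954	0
finns	10816	13:32380000:A:G	1	21632	0
global	118477	11:108300000:G:C	2	236954	0
finns	10816	11:108300000:G:C	1	21632	0
global	118477	3:142562000:TACCATTGTCCTGAG:T	1	236954	0
global	118477	16:23635000:CT:C	3	236954	0
finns	10816	16:23635000:CT:C	2	21632	0
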