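variant_id	codes	printed_tier	known_discrepancy	note
11:108300000:G:C	PM1,PM2,PP5,PP2,PP3	LP	no	
3:142562000:TACCATTGTCCTGAG:T	PVS1,PM2,PP3	P	no	
13:32394600:A:G	PM1,PM2,PP3,PP5	P	yes	printed evidence satisfies only a likely-pathogenic clause; impact recorded verbatim as missense although the HGVS denotes a splice-acceptor change
13:32380000:A:G	PVS1,PM2,PP5	P	no	
22:28695000:AC:A	PVS1,PM2,PP5	P	no	
7:124510000:T:A	PVS1,PM2,PP3	P	no	
7:124481000:G:C	PP3,PM2,PP5	LP	yes	printed evidence (1 moderate + 2 supporting) satisfies no standard combining clause
7:124503000:G:A	PVS1,PP5,PM2	P	no	
16:23635000:CT:C	PVS1,PM2,PP3	P	no	
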