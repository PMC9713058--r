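family_id	individual_id	father_id	mother_id	sex	phenotype	diagnosis	tested_variant	tested_result
2	2_I.1	0	0	1	2	MM	7:124503000:G:A	untested
2	2_I.2	0	0	2	1
2	2_II.2	2_I.1	2_I.2	2	2	MM	7:124503000:G:A	carrier
2	2_II.3	0	0	1	1
2	2_III.1	2_II.3	2_II.2	2	2	MM	7:124503000:G:A	carrier
3	3_I.1	0	0	1	2	MM	7:124510000:T:A	noncarrier
3	3_I.1	0	0	1	2	MM	22:28695000:AC:A	carrier
3	3_I.1	0	0	1	2	MM	1:45330000:C:T	carrier
3	3_I.2	0	0	2	1
3	3_II.1	3_I.1	3_I.2	1	2	MM	7:124510000:T:A	carrier
3	3_II.1	3_I.1	3_I.2	1	2	MM	22:28695000:AC:A	carrier
3	3_II.1	3_I.1	3_I.2	1	2	MM	1:45330000:C:T	carrier
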