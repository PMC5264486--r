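gene_id	TSS:H2BK5ac	TSS:H3K4me3	TSS:H3K9ac
t1	1	1	1
t2	1	1	0
t3	1	0	1
t4	0	0	0
t5	0	0	1
t6	0	0	0
t7	0	0	1
t8	1	0	0
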