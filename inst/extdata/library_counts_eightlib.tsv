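library_id	tissue_class	reads_mapped	regions_mapped	insertion_reads	insertion_regions
NC1	normal	245825	31871	56	28
NC2	normal	460438	47071	692	159
PA1	tumor	256014	31683	78	36
PA2	tumor	238633	33760	216	61
PA3	tumor	336103	41485	453	113
PA4	tumor	283730	33937	203	62
PA5	tumor	276505	33052	23	16
RL	tumor	245600	36957	41	23
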