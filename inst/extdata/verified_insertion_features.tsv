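locus_id	coordinate	subfamily	tsd	cleavage_site	polya_region
AI-1	chr15:61216453-61216621	AluY	AAGAAATGTTCT	TTAA	CTCAAAAAAAAAAAAAAAGAAAAAAAAAAAAGAAAAAAGAAAT
AI-2	chr5:139595078-139595241	AluYb8	TAAATTACAGA	TTAAA	CTCAAAAAAAAAAAAAAAATAAATAAATAAATAAATTA
AI-3	chr4:41598260-41598327	AluY	AAGTACATGTGG	TGGAA	CTCAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAGT
AI-4	chr13:23662855-23663027	AluYa5	CATCTG	TTAAAA	CTCCGTCTCAAAAAAAAAAAAAACAAAAAAAAAAACAAAAAAAAAAAACATCT
AI-5	chr15:28179309-28179438	AluY	ATAAAACATGGTCTG	TATAAAA	CTCAAAAAAAAAAAAAAAATAAAAAAAAATAAATAAAAAAATAAAACAT
AI-6	chr12:32076361-32076491	AluYg6	GAAATAATTGATCT	TGAAA	CTCAAAAAAAAAAAAAAAAAAAAAGAAATAAT
AI-7	chr11:130675880-130675924	AluY	AAAAAGAAGC	TTAAAA	CTCAAAAAAAAAAAAAAAAAAAAGAAGCA
AI-8	chr5:141758572-141758694	AluYb8	AAAAATGGGGATT	TTAAAA	CTCAAAAAAAAAAAAAAAAAATGGGGA
AI-9	chr10:107891481-107891638	AluYg6	CGTGTGCTC	TTAAAA	CTCAAAAAAAAAAACGTGTG
AI-10	chr10:72605338-72605440	AluYg6	AAGAAGGTA	TAA	CTCAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAGGT
AI-11	chr2:48276482-48276601	AluYb8	AGAAATTCAAATGCA	TTA	CTCAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAT
AI-12	chr5:16716576-16716677	AluYg6	AAGAAGTATGACAG	TAA	CTCAAAAAAAAAAAAAAAAAAAAGAAGTAT
AI-13	chr12:24518543-24518646	AluY	AAAAAAGTATTAATCA	TTAAAA	CTCAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGTAT
AI-14	chr6:57403535-57403610	AluY	TCCTA	TAAT	CTCAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAATTCC
AI-15	chr2:9888790-9888862	AluYb8	CACACCCGTG	TAA	CTCAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAACACAC
AI-16	chr9:1631754-1631884	AluYb8	AAGAA	CAAA	CTCAAAAAAAAAAAAAAAAAAAAAGAAAACA
AI-17	chr4:139225139-139225274	AluY	GAGTTTTTAAACATCT	TTAAA	CTCAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGGAGT
AI-18	chr2:26623669-26623732	AluYb8	AAAATCAGTTCTTCC	TTAAAA	CTCAAAAAAAAAAAAAAAAAAAAAAAAAAAAAATCAGTT
AI-19	chr9:37594172-37594310	AluY	AAGAAGTAGATATGG	TAA	CTCCAAAAAAAAAAAAAAGAAG
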