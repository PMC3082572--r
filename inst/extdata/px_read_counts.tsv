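individual_id	sex	mid	reads
Father	M	CGATA	297795
Mother	F	CGGCG	495190
Control_1	F	CTAGG	474048
Control_2	M	CTGAA	381912
Control_3	F	GAAGC	467094
Control_4	M	GAGAT	496749
Control_5	M	GCATT	16959
Control_6	M	GGAAG	510666
Control_7	M	GTACA	842036
Control_8	F	TAATG	414966
Control_9	F	TAGCA	462595
Control_10	F	TCAGA	325581
Bioassay_1	M	TCGAG	510086
Bioassay_2	M	TGACC	609811
Bioassay_3	M	TGGTT	374328
Bioassay_4	M	TTAAT	168157
Bioassay_5	M	AACCC	375236
Bioassay_6	F	ACTGC	373667
Bioassay_7	F	AAGGG	513757
Bioassay_8	F	ACGTA	463518
Bioassay_9	M	AGAGT	638261
Bioassay_10	M	ATGCT	482003
Bioassay_11	M	CAGTC	476704
Bioassay_12	F	CCAAC	45955
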