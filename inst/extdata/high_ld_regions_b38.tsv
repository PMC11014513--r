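chrom	start_bp	end_bp	label
1	47761741	51822307	high_ld
2	129125957	139525961	LCT
2	182309767	189427029	high_ld
3	47483506	49987563	high_ld
3	83368159	86868160	high_ld
3	161899518	163699518	high_ld
5	98636396	101136397	high_ld
5	129636408	132636409	high_ld
5	136136412	139136412	high_ld
6	23691793	38924246	HLA
6	139637170	142137170	high_ld
8	6455071	13598120	inversion_8p23
8	110918595	113918595	high_ld
11	88127184	91127184	high_ld
12	110577812	113099475	high_ld
14	47061047	47961047	high_ld
17	42394456	46567318	inversion_17q21
20	33948533	36438183	high_ld
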