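species	pair	lib4_1to10	lib5_1to50
pig	12S_KH	26	7
horse	12S_KH	6	1
cattle	12S_KH	1681	1554
sheep	12S_KH	193	174
rabbit	12S_KH	1698	1587
human	12S_KH	1559	1494
rat	12S_KH	98	100
pig	16S_KH	21	8
horse	16S_KH	1	0
cattle	16S_KH	1650	1728
sheep	16S_KH	156	196
rabbit	16S_KH	746	817
human	16S_KH	467	558
rat	16S_KH	69	84
pig	16S_Ki	30	12
horse	16S_Ki	26	17
cattle	16S_Ki	4949	3429
sheep	16S_Ki	561	375
rabbit	16S_Ki	4103	2830
human	16S_Ki	6430	4596
rat	16S_Ki	540	286
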