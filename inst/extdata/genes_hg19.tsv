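name	chrom	start	end
KRAS	chr12	25358180	25403854
MET	chr7	116312459	116438440
ERBB2	chr17	37844167	37886679
EGFR	chr7	55086725	55324313
BRAF	chr7	140419127	140624564
PIK3CA	chr3	178866311	178952497
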