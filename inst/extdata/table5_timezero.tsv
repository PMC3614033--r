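# Alleles already present in the time-zero strain: excluded from the causal
# table even though they segregated above the 90% read-fraction threshold.
clone	allele
EvoClone2	ira1-F664I
EvoClone8	phm8-I97N
EvoClone8	rpl37a(-52T->G)
EvoClone8	vta1-A247V
EvoClone8	yor1-E393D
EvoClone9	vta1-A247V
EvoClone10	aim32-E241G
EvoClone10	irs4-N257S
EvoClone10	nnt1(-427T->C)
EvoClone10	prp9-N155S
EvoClone10	yrb1-N120I
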