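# Putative causal alleles that ended below 5% of the final evolved population
# and therefore do not appear in the Sanger time-course figures.
clone	allele
EvoClone7C	puf4-Q654*
EvoClone8	mit1-W63*
EvoClone9	mcd1-S175L
EvoClone10	top3-V560A
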