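# Mutations judged to have hitchhiked (excluded from the causal table) and the
# putative causal allele each is genetically linked to.
clone	hitchhiker	linked_to
EvoClone3	atg4	sin4
EvoClone7A	slx4 promoter	ace2
EvoClone7B	thi3	ram1
EvoClone7B	crt10	ira2
EvoClone8	crh1 promoter	ubr1
EvoClone9	brr1	MED1
EvoClone9	nsp1 promoter	irc8
EvoClone10	pri2 promoter	rgt1
EvoClone10	ino80	nut1
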