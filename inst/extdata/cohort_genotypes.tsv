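patient_id	paternal_allele	maternal_allele
3310066-1		
3310615-1		
3312024-1	c.279T>A	Exons 1-3 deletion (7666 bp)
3312051-1		
3312061-1	c.1264-6T>G	Exons 1-3 deletion (7666 bp)
3312177-1	c.919-2A>G	Exons 5-6 deletion (1845 bp)
3312180-1	Exons 1-3 deletion (7666 bp)	c.1667A>G
3312189-1	Exons 9-10 deletion (4979 bp)	c.1614+1G>A
3312285-1	Exons 5-6 deletion (1845 bp)	Exons 5-6 deletion (1845 bp)
3312305-1	c.304+941C>T	c.946G>T
3312396-1	c.1315G>A	c.304+941C>T
3312635-1	c.2168A>G	
3312757-1	Exons 1-3 deletion (3152 bp)	c.919-2A>G
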