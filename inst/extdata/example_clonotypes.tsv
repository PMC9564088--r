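cdr3_nt	read_count	chain	v_gene	j_gene
TGTCAGCAAAGTTACAGTATTCCTCGGACGTTC	120	IGK	IGKV3-20	IGKJ1
TGTCAGCAAAGTTACAGTATTCCTCGGACCTTC	8	IGK	IGKV3-20	IGKJ1
TGTCAGCAAAGTTACAGTATTCCACGGACGTTC	3	IGK	IGKV3-20	IGKJ1
CAGCAGTATGGTAGCTCACCGGCGACG	55	IGK	IGKV1-5	IGKJ2
CAGCAGTATGGTAGCTCACCGGCGACC	4	IGK	IGKV1-5	IGKJ2
TGTCAGCAGATTGATACCTGGCCTCGAACCTTC	40	IGK	IGKV1-39	IGKJ4
TGTCTGCAGCATAATAGATACCCGCTCACTTTC	17	IGK	IGKV2-28	IGKJ3
TGTGGGACTTGGGATTCCAGCCTGAGTGCTTAT	9	IGL	IGLV2-14	IGLJ2
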