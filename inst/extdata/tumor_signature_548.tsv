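cdr3_nt	fraction
TGTCAGCAGATTGATACCTGGCCTCGAACCTTC	0.973
TGTCTGCAGCATAATAGATACCCGCTCACTTTC	0.006
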