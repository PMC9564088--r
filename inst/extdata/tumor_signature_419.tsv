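cdr3_nt	fraction
TGTCAGCAAAGTTACAGTATTCCTCGGACGTTC	0.862
TGTCAGCAAAGTTACAGTATTCCTCGGACCTTC	0.079
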