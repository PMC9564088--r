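cdr3_nt	fraction
CAGCAGTATGGTAGCTCACCGGCGACG	0.925
CAGCAGTATGGTAGCTCACCGGCGACC	0.064
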