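name	forward	reverse	probe	declared_length
PxhG1	GCCACTAATTGGTTATGC	GGATGGCATGACAGTAA	CAGTGCTGCCATAACCATGAGTG	93
PxhG2	GCCAGTGCTCAAACTTAA	CTGGATCGGCAATTCAAA	CACCTTGGAGGATGACCGCC	100
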