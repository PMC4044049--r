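# toy three-domain taxonomy: C = cellular organisms, A = archaea,
# B = bacteria, E = eukaryotes; A1..A3 and B1..B2 are sub-taxa
A	C
B	C
E	C
A1	A
A2	A
A3	A
B1	B
B2	B
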