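seq_id	taxon_id	score	evalue
s01	A1	412.0	1.2e-115
s02	A1	398.5	4.0e-111
s03	A1	371.2	2.1e-103
s04	A1	305.9	6.5e-84
s05	A2	362.4	8.8e-101
s06	A2	344.0	3.3e-95
s07	A2	290.1	4.7e-79
s08	A3	277.6	2.9e-75
s09	B1	255.8	1.1e-68
s10	B1	213.3	7.4e-56
s11	B2	188.0	2.6e-48
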