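1	|	1	|	no rank	|
131567	|	1	|	no rank	|
2	|	131567	|	superkingdom	|
2157	|	131567	|	superkingdom	|
2759	|	131567	|	superkingdom	|
1224	|	2	|	phylum	|
1236	|	1224	|	class	|
91347	|	1236	|	order	|
543	|	91347	|	family	|
561	|	543	|	genus	|
562	|	561	|	species	|
590	|	543	|	genus	|
28901	|	590	|	species	|
1239	|	2	|	phylum	|
91061	|	1239	|	class	|
1385	|	91061	|	order	|
186817	|	1385	|	family	|
1386	|	186817	|	genus	|
1423	|	1386	|	species	|
1117	|	2	|	phylum	|
1161	|	1117	|	order	|
1177	|	1161	|	genus	|
103690	|	1177	|	species	|
201174	|	2	|	phylum	|
1760	|	201174	|	class	|
2037	|	1760	|	order	|
1654	|	2037	|	genus	|
28890	|	2157	|	phylum	|
183939	|	28890	|	class	|
2182	|	183939	|	order	|
2184	|	2182	|	genus	|
2188	|	2184	|	species	|
28889	|	2157	|	phylum	|
2281	|	28889	|	order	|
2284	|	2281	|	genus	|
2287	|	2284	|	species	|
33090	|	2759	|	kingdom	|
35493	|	33090	|	phylum	|
3700	|	35493	|	family	|
3701	|	3700	|	genus	|
3702	|	3701	|	species	|
4751	|	2759	|	kingdom	|
4890	|	4751	|	phylum	|
4930	|	4890	|	genus	|
4932	|	4930	|	species	|
33208	|	2759	|	kingdom	|
7711	|	33208	|	phylum	|
9605	|	7711	|	genus	|
9606	|	9605	|	species	|
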