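seq_id	taxon_id	score	evalue
prot001	2188	468	1.58e-47
prot002	2287	462.4	5.75e-47
prot003	28901	456.3	2.34e-46
prot004	1654	451.5	7.08e-46
prot005	9606	447	2e-45
prot006	28901	433.7	4.27e-44
prot007	28901	426.5	2.24e-43
prot008	1423	424.5	3.55e-43
prot009	28901	413.9	4.07e-42
prot010	103690	405.2	3.02e-41
prot011	3702	390	1e-39
prot012	2188	369	1.26e-37
prot013	2287	361.6	6.92e-37
prot014	103690	357.5	1.78e-36
prot015	562	350.1	9.77e-36
prot016	2188	349.6	1.1e-35
prot017	2287	338.5	1.41e-34
prot018	4932	331.4	7.24e-34
prot019	103690	321.3	7.41e-33
prot020	3702	317.8	1.66e-32
prot021	2287	306.7	2.14e-31
prot022	3702	303.1	4.9e-31
prot023	562	294.3	3.72e-30
prot024	3702	263.3	4.68e-27
prot025	103690	260.7	8.51e-27
prot026	562	254.7	3.39e-26
prot027	562	254.2	3.8e-26
prot028	4932	224.6	3.47e-23
prot029	3702	205.3	2.95e-21
prot030	1423	197.3	1.86e-20
prot031	9606	196.1	2.45e-20
prot032	2188	189.5	1.12e-19
prot033	4932	187.7	1.7e-19
prot034	9606	183.5	4.47e-19
prot035	1423	181.9	6.46e-19
prot036	1423	180	1e-18
prot037	9606	177.2	1.91e-18
prot038	1654	159.8	1.05e-16
prot039	9606	151.5	7.08e-16
prot040	1654	143.9	4.07e-15
prot041	562	140.6	8.71e-15
prot042	103690	136.9	2.04e-14
prot043	1423	135.7	2.69e-14
prot044	2188	111.2	7.59e-12
prot045	2287	105.2	3.02e-11
prot046	1654	94.9	3.24e-10
prot047	1654	90.5	8.91e-10
prot048	4932	73.7	4.27e-08
prot049	28901	68.9	1.29e-07
prot050	4932	67.5	1.78e-07
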