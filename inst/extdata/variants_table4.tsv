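# Disease-associated TTN M-band missense variants (printed annotation table).
# structure/impact columns are the published expert annotations; empty impact
# cells are encoded as NA. stability = predicted stability change (kcal/mol).
domain	wt	mut	uniprot_position	local_index	frequency	stability	reference	conservation_flag	structure	impact
M1	G	R	32510	21	8.28e-06	-0.638	rs191522469	NA	Loop	Altered loop conformation
M1	I	V	32558	69	0.004253	-1.471	rs56347248	NA	Hydrophobic core	NA
M3	E	Q	32742	27	0.003337	-0.821	rs148525155	NA	Surface	NA
M3	I	N	32770	55	8.3e-06	-2.402	rs72629784	NA	Hydrophobic core	Fold destabilization
M3	T	M	32790	75	0.0006962	0.153	rs192001910	NA	Loop	NA
M4	G	D	33315	21	8.28e-06	-3.034	rs145748940	C	Loop	Altered loop conformation
M4	H	Y	33364	70	8.29e-06	0.777	rs116876353	NA	Loop	NA
M4	T	M	33387	93	8.29e-06	-0.162	rs56001826	NA	Surface	NA
M4	D	E	33389	95	8.28e-06	-0.179	rs72629789	NA	Surface	NA
M5	V	M	33536	54	0.00308	-0.711	rs55865284	NA	Hydrophobic core	Fold destabilization
M5	K	Q	33568	86	1.66e-05	0.167	rs56365812	S	β-strand, exposed	NA
M10	C	S	34277	28	8.45e-06	-1.373	rs193212275	S	Hydrophobic core	NA
M10	C	Y	34277	28	0.000101	-1.373	rs193212275	S	Hydrophobic core	Fold destabilization
M10	E	Y	34286	37	NA	NA	lit	NA	β-strand, exposed	NA
M10	V	K	34287	38	NA	NA	lit	NA	Hydrophobic core	NA
M10	T	E	34288	39	NA	NA	lit	NA	β-strand, exposed	NA
M10	W	K	34289	40	NA	NA	lit	C	Hydrophobic core	NA
M10	W	R	34289	40	NA	-2.172	lit	C	Hydrophobic core	Fold destabilization
M10	H	P	34305	56	NA	-0.76	lit	NA	Loop	Altered loop conformation
M10	I	N	34306	57	NA	-1.845	lit	NA	Hydrophobic core	Fold destabilization
M10	L	P	34315	66	NA	-1.745	lit	NA	Hydrophobic core	Fold destabilization
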