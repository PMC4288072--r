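entity_class	count_annphy	count_annling	count_comb	count_tie	kappa_strict	kappa_unstrict	f1_all_features
Medication	1231	1278	1152	1286	0.92	0.95	0.83
Dosage	143	315	137	205	0.59	0.82	0.61
Route	115	244	107	132	0.59	0.64	0.32
Frequency	25	56	21	42	0.58	0.74	0.59
Duration	34	153	24	51	0.34	0.87	0.34
Indication	175	148	126	175	0.76	0.93	0.65
AdverseEvent	1689	2083	1646	1842	0.83	0.93	0.72
OSSD	234	140	90	147	0.50	0.71	0.55
Treatment	77	216	62	153	0.39	0.77	0.60
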