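# Per-module support values for seven epilepsy formulas against the
# main-indication drug module and six side-effect drug modules, with the
# reported weighted-average row (50% main weight, remainder split equally).
# Note: the reported F2 cell (0.68) does not equal the aggregation of its own
# per-module rows (0.674...), which was evidently computed before rounding.
module	role	F1	F2	F3	F4	F5	F6	F7
Epilepsy	main	0.84	0.78	0.78	0.61	0.65	0.32	0.78
Somnolence	side_effect	0.44	0.44	0.50	0.44	0.50	0.31	0.50
Fatigue	side_effect	0.43	0.41	0.43	0.38	0.43	0.22	0.43
Skin rash	side_effect	0.70	0.70	0.70	0.70	0.70	0.25	0.70
Nausea	side_effect	0.72	0.66	0.70	0.51	0.53	0.13	0.68
Insomnia	side_effect	0.69	0.66	0.66	0.49	0.52	0.16	0.65
Tremor	side_effect	0.62	0.54	0.58	0.46	0.50	0.17	0.58
Support (weighted avg.)	reported_weighted_avg	0.72	0.68	0.69	0.55	0.59	0.26	0.69
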