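# Per-module support values for ten anxiety formulas against the
# main-indication drug module and four side-effect drug modules, with the
# reported weighted-average row (50% main weight, remainder split equally).
module	role	F1	F2	F3	F4	F5	F6	F7	F8	F9	F10
Anxiety	main	0.63	0.59	0.67	0.67	0.81	0.26	0.59	0.89	0.70	0.91
Fatigue	side_effect	0.44	0.44	0.44	0.44	0.44	0.22	0.44	0.44	0.44	0.44
Hypotension	side_effect	0.66	0.70	0.70	0.62	0.70	0.13	0.70	0.66	0.75	0.66
Somnolence	side_effect	0.5	0.5	0.5	0.5	0.5	0.31	0.5	0.5	0.5	0.5
Constipation	side_effect	0.69	0.69	0.66	0.60	0.67	0.29	0.66	0.64	0.69	0.67
Support (weighted avg.)	reported_weighted_avg	0.60	0.59	0.62	0.61	0.69	0.25	0.58	0.73	0.65	0.74
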