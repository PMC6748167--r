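sample_id	group	age	glial_proportion
S001	control	92.9	0.432
S002	control	84.9	0.436
S003	control	83.1	0.65
S004	control	71.9	0.653
S005	control	81.4	0.593
S006	case	82.1	0.479
S007	case	70.4	0.328
S008	case	62.5	0.678
S009	case	72.6	0.643
S010	case	68.7	0.588
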