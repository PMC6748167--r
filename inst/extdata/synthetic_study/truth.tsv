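probe_id	scenario	effect_mc	effect_hmc	effect_interaction
probe_00001	null	0	0	0
probe_00002	null	0	0	0
probe_00003	null	0	0	0
probe_00004	null	0	0	0
probe_00005	A	-1.2	0.4	1.6
probe_00006	B	-0.8	0.644389197400643	1.44438919740064
probe_00007	null	0	0	0
probe_00008	null	0	0	0
probe_00009	null	0	0	0
probe_00010	null	0	0	0
probe_00011	null	0	0	0
probe_00012	null	0	0	0
probe_00013	null	0	0	0
probe_00014	null	0	0	0
probe_00015	null	0	0	0
probe_00016	null	0	0	0
probe_00017	null	0	0	0
probe_00018	null	0	0	0
probe_00019	null	0	0	0
probe_00020	null	0	0	0
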