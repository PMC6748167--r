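probe_id	S001	S002	S003	S004	S005	S006	S007	S008	S009	S010
probe_00001	0.06	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00002	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00003	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00004	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00005	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00006	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00007	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00008	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00009	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00010	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00011	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00012	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00013	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00014	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00015	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00016	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00017	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00018	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00019	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
probe_00020	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01	0.01
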