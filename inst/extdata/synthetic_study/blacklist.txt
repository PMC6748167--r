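probe_00002
probe_absent
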