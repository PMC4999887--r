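channel	114	115	116	117
114	0.929	0.02	0	0
115	0.059000000000000004	0.923	0.03	0.001
116	0.002	0.055999999999999994	0.924	0.04
117	0	0.001	0.045	0.923
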