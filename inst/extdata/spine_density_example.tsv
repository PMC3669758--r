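type	bin_start	bin_end	density
all	0	30	0.3
all	30	100	1.2
all	100	1000000	0.8
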