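species	k	n
American herring gull	16	94
Great black-backed gull	1	38
Iceland gull	0	4
Ring-billed gull	0	9
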