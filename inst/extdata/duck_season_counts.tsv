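season	k	n
February-May	23	41
September-November	9	72
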