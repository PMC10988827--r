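CP:0000041
CP:0000043
CP:0000045
CP:0000042
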