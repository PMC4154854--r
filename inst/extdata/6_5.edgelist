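# 6_5
n=6
1 2
2 3
2 4
2 6
4 5
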