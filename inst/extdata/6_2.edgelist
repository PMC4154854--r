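# 6_2
n=6
1 2
2 3
2 4
4 5
5 6
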