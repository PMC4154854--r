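# 10_19
n=10
1 2
1 7
2 3
2 5
3 4
6 7
7 8
8 9
9 10
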