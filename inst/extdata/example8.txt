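1 | 2 3 4 5 6 7 8
1 3 4 5 6 7 8 | 2
1 2 4 5 6 7 8 | 3
1 2 3 5 6 7 8 | 4
1 2 3 4 6 7 8 | 5
1 2 3 4 5 7 8 | 6
1 2 3 4 5 6 8 | 7
1 2 3 4 5 6 7 | 8
1 8 | 2 3 4 5 6 7
1 2 5 6 7 8 | 3 4
1 2 3 4 7 8 | 5 6
1 2 3 4 5 6 | 7 8
1 7 8 | 2 3 4 5 6
1 5 6 7 8 | 2 3 4
1 2 6 7 8 | 3 4 5
1 6 7 8 | 2 3 4 5
1 2 7 8 | 3 4 5 6
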