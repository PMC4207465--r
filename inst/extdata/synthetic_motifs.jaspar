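>SYN0001.1 SYNTF_A
A  [ 10  0  0 10  2 ]
C  [  0  0 10  0  2 ]
G  [  0 10  0  0  2 ]
T  [  0  0  0  0  4 ]
>SYN0002.1 SYNTF_B
A  1 8 1
C  1 0 1
G  7 1 1
T  1 1 7
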