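ID SYNTF_A
BF synthetic test motif
XX
P0      A      C      G      T
01     10      0      0      0
02      0      0     10      0
03      0     10      0      0
04     10      0      0      0
05      2      2      2      4
XX
//
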