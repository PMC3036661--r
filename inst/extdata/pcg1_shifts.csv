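beat,shift_samples
1,0
2,-679
3,102
4,-1018
5,33
6,-1087
7,135
8,-985
9,271
10,-849
11,-68
12,-747
13,304
14,-816
15,-35
16,-714
17,61
18,-1059
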