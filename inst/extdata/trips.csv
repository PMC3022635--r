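distance_m,count
1000,14
2000,78
3000,160
4000,243
5000,251
6000,209
7000,146
8000,93
9000,53
10000,27
11000,13
12000,6
13000,2
14000,1
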