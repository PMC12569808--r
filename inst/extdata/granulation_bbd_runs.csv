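run,diluent,ethanol,binder,molding_rate
1,14,80,12,94.23
2,10,80,10,91.67
3,10,85,12,83.96
4,10,90,10,67.52
5,6,85,14,83.67
6,10,85,12,85.07
7,6,85,10,81.40
8,14,85,10,78.44
9,10,90,14,76.62
10,6,90,12,74.09
11,14,85,14,81.10
12,10,85,12,84.87
13,14,90,12,70.45
14,10,80,14,92.27
15,6,80,12,92.56
16,10,85,12,84.14
17,10,85,12,82.12
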