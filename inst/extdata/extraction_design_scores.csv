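run,water_ratio,extraction_count,duration_h,score
1,1:10,1,1,71.59
2,1:10,2,3,26.21
3,1:10,3,2,54.18
4,1:15,1,3,25.15
5,1:15,2,2,25.62
6,1:15,3,1,38.90
7,1:20,1,2,74.45
8,1:20,2,1,63.52
9,1:20,3,3,46.76
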