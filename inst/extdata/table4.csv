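volunteer_id,actual_bpm,predicted_bpm,printed_error_percent
1,72,72,0
2,92,92,0
3,95,94,1.052
4,78,78,0
5,102,102,0
6,69,69,0
7,82,82,0
8,76,76,0
9,62,60,3.226
10,67,67,0
11,89,89,0
12,96,96,0
13,74,74,0
14,84,84,0
15,71,71,0
16,64,64,0
17,83,83,0
18,93,93,0
19,81,81,0
20,78,78,0
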