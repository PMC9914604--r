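volunteer_id,actual_bpm,predicted_bpm,printed_error_percent
1,72,72,0
2,92,92,0
3,95,95,0
4,78,78,0
5,102,101,0.980
6,69,69,0
7,82,81,1.22
8,76,76,0
9,62,62,0
10,67,67,0
11,89,89,0
12,96,95,1.041
13,74,73,1.35
14,84,84,0
15,71,71,0
16,64,62,3.125
17,83,82,1.205
18,93,93,0
19,81,81,0
20,78,78,0
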