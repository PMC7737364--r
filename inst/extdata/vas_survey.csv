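respondent_id,vas_no_chemo,vas_first_line,vas_second_line
1,95,85,75
2,95,75,50
3,80,70,65
4,95,70,50
5,95,70,50
6,90,70,50
7,95,80,50
8,100,80,60
9,90,85,60
10,95,80,65
11,90,80,60
12,90,70,50
13,90,80,70
14,85,58,37
15,100,90,87
16,100,100,96
17,100,99,93
18,95,70,45
19,100,80,50
20,85,70,50
21,95,75,50
22,90,80,40
23,95,85,60
24,90,80,60
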