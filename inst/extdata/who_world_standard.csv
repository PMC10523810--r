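age_group,weight
0-4,0.0885690008497025949
5-9,0.0868695956415254655
10-14,0.0859699105313140449
15-19,0.0846703653721197630
20-24,0.0821712400659769110
25-29,0.0792722547108511977
30-34,0.0760733743189883627
35-39,0.0714749837556855200
40-44,0.0658769430699255309
45-49,0.0603788673964112607
50-54,0.0536812115759484204
55-59,0.0454840805717998675
60-64,0.0371869845554056097
65-69,0.0295896436247313453
70-74,0.0220922677063027928
75-79,0.0151946818613485288
80-84,0.0090968161143599752
85+,0.0063477782776028393
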