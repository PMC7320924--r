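scope,group,stage,n
age,30-34,I,254
age,30-34,II,27
age,30-34,III-IV,16
age,35-39,I,396
age,35-39,II,43
age,35-39,III-IV,29
age,40-44,I,538
age,40-44,II,59
age,40-44,III-IV,36
age,45-49,I,599
age,45-49,II,79
age,45-49,III-IV,45
age,50-54,I,592
age,50-54,II,108
age,50-54,III-IV,50
age,55-59,I,717
age,55-59,II,139
age,55-59,III-IV,82
age,60-64,I,818
age,60-64,II,193
age,60-64,III-IV,73
age,65-69,I,1009
age,65-69,II,256
age,65-69,III-IV,98
age,70-74,I,837
age,70-74,II,298
age,70-74,III-IV,98
age,75-79,I,685
age,75-79,II,298
age,75-79,III-IV,90
age,80-84,I,472
age,80-84,II,323
age,80-84,III-IV,61
age,85-89,I,290
age,85-89,II,270
age,85-89,III-IV,28
age,90+,I,95
age,90+,II,180
age,90+,III-IV,21
region,Q1,I,973
region,Q1,II,418
region,Q1,III-IV,110
region,Q2,I,1362
region,Q2,II,490
region,Q2,III-IV,139
region,Q3,I,1457
region,Q3,II,469
region,Q3,III-IV,159
region,Q4,I,1574
region,Q4,II,447
region,Q4,III-IV,140
region,Q5,I,1936
region,Q5,II,449
region,Q5,III-IV,179
gothenburg,Q1,I,61
gothenburg,Q1,II,41
gothenburg,Q1,III-IV,8
gothenburg,Q2,I,186
gothenburg,Q2,II,59
gothenburg,Q2,III-IV,17
gothenburg,Q3,I,192
gothenburg,Q3,II,74
gothenburg,Q3,III-IV,13
gothenburg,Q4,I,234
gothenburg,Q4,II,61
gothenburg,Q4,III-IV,15
gothenburg,Q5,I,344
gothenburg,Q5,II,71
gothenburg,Q5,III-IV,18
malmoe,Q1,I,24
malmoe,Q1,II,23
malmoe,Q1,III-IV,7
malmoe,Q2,I,67
malmoe,Q2,II,27
malmoe,Q2,III-IV,12
malmoe,Q3,I,85
malmoe,Q3,II,29
malmoe,Q3,III-IV,6
malmoe,Q4,I,111
malmoe,Q4,II,35
malmoe,Q4,III-IV,15
malmoe,Q5,I,134
malmoe,Q5,II,36
malmoe,Q5,III-IV,19
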