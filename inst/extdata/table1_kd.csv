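glycan,lectin,kd,ratio_to_Con-anc,ratio_to_ConI
01,ConI,0.50,10,1
02,ConI,0.36,7,1
03,ConI,0.24,7,1
04,ConI,0.36,7,1
05,ConI,0.58,8,1
06,ConI,0.51,8,1
09,ConI,0.51,9,1
10,ConI,0.42,6,1
11,ConI,0.37,7,1
21,ConI,1.2,10,1
22,ConI,1.4,11,1
23,ConI,-,-,-
41,ConI,0.96,8,1
42,ConI,0.31,8,1
43,ConI,0.35,6,1
26,ConI,6.8,4,1
27,ConI,-,-,-
28,ConI,2.8,17,1
29,ConI,-,-,-
30,ConI,-,-,-
31,ConI,-,-,-
32,ConI,4.5,8,1
33,ConI,-,-,-
34,ConI,6.4,8,1
38,ConI,-,-,-
39,ConI,2.3,24,1
40,ConI,-,-,-
44,ConI,4.4,13,1
45,ConI,13,13,1
46,ConI,9.4,5,1
47,ConI,3.8,9,1
48,ConI,17,3,1
49,ConI,10,6,1
50,ConI,-,-,-
01,ConII,3.8,1.4,0.13
02,ConII,2.3,1.0,0.15
03,ConII,1.4,1.1,0.17
04,ConII,2.3,1.1,0.16
05,ConII,4.0,1.1,0.14
06,ConII,3.4,1.2,0.15
09,ConII,3.8,1.2,0.13
10,ConII,2.5,1.1,0.17
11,ConII,2.3,1.1,0.16
21,ConII,9.6,1.3,0.13
22,ConII,12,1.3,0.12
23,ConII,-,-,-
41,ConII,9.4,0.8,0.10
42,ConII,2.5,1.0,0.12
43,ConII,2.5,0.8,0.14
26,ConII,28,1.0,0.25
27,ConII,-,-,-
28,ConII,26,1.8,0.11
29,ConII,51,4.7,-
30,ConII,66,3.0,-
31,ConII,-,-,-
32,ConII,18,2.0,0.25
33,ConII,-,-,-
34,ConII,25,1.9,0.26
38,ConII,-,-,-
39,ConII,31,1.7,0.07
40,ConII,75,0.8,-
44,ConII,24,2.3,0.18
45,ConII,122,1.4,0.11
46,ConII,37,1.2,0.26
47,ConII,43,0.8,0.09
48,ConII,42,1.3,0.40
49,ConII,44,1.4,0.23
50,ConII,-,-,-
01,Con-anc,5.2,1,0.10
02,Con-anc,2.4,1,0.15
03,Con-anc,1.6,1,0.15
04,Con-anc,2.5,1,0.15
05,Con-anc,4.6,1,0.13
06,Con-anc,4.0,1,0.13
09,Con-anc,4.7,1,0.11
10,Con-anc,2.7,1,0.16
11,Con-anc,2.5,1,0.15
21,Con-anc,13,1,0.10
22,Con-anc,15,1,0.09
23,Con-anc,-,-,-
41,Con-anc,7.7,1,0.12
42,Con-anc,2.6,1,0.12
43,Con-anc,2.0,1,0.18
26,Con-anc,27,1,0.26
27,Con-anc,-,-,-
28,Con-anc,46,1,0.06
29,Con-anc,242,1,-
30,Con-anc,196,1,-
31,Con-anc,-,-,-
32,Con-anc,37,1,0.12
33,Con-anc,-,-,-
34,Con-anc,49,1,0.13
38,Con-anc,-,-,-
39,Con-anc,54,1,0.04
40,Con-anc,63,1,-
44,Con-anc,55,1,0.08
45,Con-anc,171,1,0.08
46,Con-anc,44,1,0.21
47,Con-anc,34,1,0.11
48,Con-anc,56,1,0.30
49,Con-anc,62,1,0.16
50,Con-anc,-,-,-
01,Con-anc-N/C,13,0.41,0.04
02,Con-anc-N/C,7.1,0.34,0.05
03,Con-anc-N/C,4.9,0.33,0.05
04,Con-anc-N/C,7.6,0.33,0.05
05,Con-anc-N/C,14,0.32,0.04
06,Con-anc-N/C,12,0.35,0.04
09,Con-anc-N/C,14,0.34,0.04
10,Con-anc-N/C,8.0,0.33,0.05
11,Con-anc-N/C,7.3,0.34,0.05
21,Con-anc-N/C,33,0.39,0.04
22,Con-anc-N/C,46,0.32,0.03
23,Con-anc-N/C,-,-,-
41,Con-anc-N/C,23,0.34,0.04
42,Con-anc-N/C,6.5,0.40,0.05
43,Con-anc-N/C,5.5,0.36,0.06
26,Con-anc-N/C,69,0.39,0.10
27,Con-anc-N/C,-,-,-
28,Con-anc-N/C,112,0.41,0.02
29,Con-anc-N/C,332,0.73,-
30,Con-anc-N/C,364,0.54,-
31,Con-anc-N/C,-,-,-
32,Con-anc-N/C,74,0.50,0.06
33,Con-anc-N/C,-,-,-
34,Con-anc-N/C,104,0.47,0.06
38,Con-anc-N/C,-,-,-
39,Con-anc-N/C,116,0.47,0.02
40,Con-anc-N/C,178,-,-
44,Con-anc-N/C,126,0.44,0.04
45,Con-anc-N/C,550,0.31,0.02
46,Con-anc-N/C,183,0.24,0.05
47,Con-anc-N/C,115,0.30,0.03
48,Con-anc-N/C,166,0.34,0.10
49,Con-anc-N/C,158,0.39,0.06
50,Con-anc-N/C,-,-,-
01,Con-anc-L5,3.2,1.6,0.16
02,Con-anc-L5,2.0,1.2,0.18
03,Con-anc-L5,1.3,1.2,0.18
04,Con-anc-L5,1.9,1.3,0.19
05,Con-anc-L5,3.2,1.4,0.18
06,Con-anc-L5,2.6,1.6,0.20
09,Con-anc-L5,3.0,1.6,0.17
10,Con-anc-L5,2.0,1.3,0.20
11,Con-anc-L5,2.0,1.3,0.19
21,Con-anc-L5,6.7,1.9,0.18
22,Con-anc-L5,7.8,1.9,0.18
23,Con-anc-L5,-,-,-
41,Con-anc-L5,3.5,2.2,0.28
42,Con-anc-L5,1.3,2.0,0.24
43,Con-anc-L5,1.4,1.4,0.26
26,Con-anc-L5,18,1.5,0.37
27,Con-anc-L5,-,-,-
28,Con-anc-L5,20,2.2,0.13
29,Con-anc-L5,168,1.4,-
30,Con-anc-L5,190,1.0,-
31,Con-anc-L5,-,-,-
32,Con-anc-L5,22,1.7,0.21
33,Con-anc-L5,-,-,-
34,Con-anc-L5,27,1.8,0.24
38,Con-anc-L5,-,-,-
39,Con-anc-L5,20,2.8,0.12
40,Con-anc-L5,136,-,-
44,Con-anc-L5,3.9,14,1.14
45,Con-anc-L5,24,7.3,0.55
46,Con-anc-L5,4.5,9.8,2.10
47,Con-anc-L5,12,2.7,0.31
48,Con-anc-L5,5.6,9.9,2.99
49,Con-anc-L5,37,1.7,0.27
50,Con-anc-L5,-,-,-
01,Con-anc-N/C/L5,1.7,3.1,0.30
02,Con-anc-N/C/L5,1.2,1.9,0.29
03,Con-anc-N/C/L5,0.78,2.1,0.31
04,Con-anc-N/C/L5,1.3,2.0,0.29
05,Con-anc-N/C/L5,2.0,2.3,0.29
06,Con-anc-N/C/L5,1.8,2.2,0.28
09,Con-anc-N/C/L5,1.9,2.4,0.26
10,Con-anc-N/C/L5,1.3,2.0,0.31
11,Con-anc-N/C/L5,1.3,1.9,0.28
21,Con-anc-N/C/L5,4.4,2.9,0.28
22,Con-anc-N/C/L5,4.2,3.5,0.32
23,Con-anc-N/C/L5,-,-,-
41,Con-anc-N/C/L5,2.2,3.5,0.43
42,Con-anc-N/C/L5,0.74,3.5,0.42
43,Con-anc-N/C/L5,0.83,2.4,0.42
26,Con-anc-N/C/L5,12,2.2,0.55
27,Con-anc-N/C/L5,-,-,-
28,Con-anc-N/C/L5,11,4.2,0.25
29,Con-anc-N/C/L5,215,1.1,-
30,Con-anc-N/C/L5,696,0.3,-
31,Con-anc-N/C/L5,-,-,-
32,Con-anc-N/C/L5,14,2.6,0.32
33,Con-anc-N/C/L5,-,-,-
34,Con-anc-N/C/L5,17,2.8,0.37
38,Con-anc-N/C/L5,-,-,-
39,Con-anc-N/C/L5,8.1,6.7,0.28
40,Con-anc-N/C/L5,94,-,-
44,Con-anc-N/C/L5,1.7,32,2.6
45,Con-anc-N/C/L5,12,15,1.1
46,Con-anc-N/C/L5,2.1,21,4.5
47,Con-anc-N/C/L5,5.6,6.1,0.69
48,Con-anc-N/C/L5,2.5,22,6.6
49,Con-anc-N/C/L5,19,3.3,0.53
50,Con-anc-N/C/L5,-,-,-
01,Con-anc-N/C/L5/L6,1.0,5.0,0.47
02,Con-anc-N/C/L5/L6,0.77,3.1,0.46
03,Con-anc-N/C/L5/L6,0.55,2.9,0.44
04,Con-anc-N/C/L5/L6,0.75,3.3,0.48
05,Con-anc-N/C/L5/L6,1.2,3.9,0.50
06,Con-anc-N/C/L5/L6,1.1,3.6,0.46
09,Con-anc-N/C/L5/L6,1.2,3.9,0.43
10,Con-anc-N/C/L5/L6,0.86,3.1,0.48
11,Con-anc-N/C/L5/L6,0.85,2.9,0.44
21,Con-anc-N/C/L5/L6,2.5,5.0,0.49
22,Con-anc-N/C/L5/L6,2.7,5.4,0.51
23,Con-anc-N/C/L5/L6,-,-,-
41,Con-anc-N/C/L5/L6,1.3,5.9,0.73
42,Con-anc-N/C/L5/L6,0.52,4.9,0.59
43,Con-anc-N/C/L5/L6,0.53,3.7,0.66
26,Con-anc-N/C/L5/L6,6.2,4.3,1.1
27,Con-anc-N/C/L5/L6,-,-,-
28,Con-anc-N/C/L5/L6,6.1,7.6,0.46
29,Con-anc-N/C/L5/L6,-,-,-
30,Con-anc-N/C/L5/L6,-,-,-
31,Con-anc-N/C/L5/L6,-,-,-
32,Con-anc-N/C/L5/L6,12,3.1,0.38
33,Con-anc-N/C/L5/L6,-,-,-
34,Con-anc-N/C/L5/L6,13,3.7,0.48
38,Con-anc-N/C/L5/L6,-,-,-
39,Con-anc-N/C/L5/L6,3.9,14,0.58
40,Con-anc-N/C/L5/L6,28,-,-
44,Con-anc-N/C/L5/L6,1.4,39,3.1
45,Con-anc-N/C/L5/L6,7.1,24,1.8
46,Con-anc-N/C/L5/L6,1.8,24,5.1
47,Con-anc-N/C/L5/L6,4.1,8.3,0.94
48,Con-anc-N/C/L5/L6,2.5,22,6.7
49,Con-anc-N/C/L5/L6,11,5.9,0.95
50,Con-anc-N/C/L5/L6,-,-,-
01,Con-anc-N/C/L5/L6/L3,0.70,7.4,0.71
02,Con-anc-N/C/L5/L6/L3,0.49,4.9,0.73
03,Con-anc-N/C/L5/L6/L3,0.39,4.1,0.62
04,Con-anc-N/C/L5/L6/L3,0.49,5.1,0.74
05,Con-anc-N/C/L5/L6/L3,0.80,5.7,0.73
06,Con-anc-N/C/L5/L6/L3,0.73,5.5,0.70
09,Con-anc-N/C/L5/L6/L3,0.74,6.4,0.69
10,Con-anc-N/C/L5/L6/L3,0.61,4.4,0.68
11,Con-anc-N/C/L5/L6/L3,0.51,4.8,0.72
21,Con-anc-N/C/L5/L6/L3,1.7,7.5,0.73
22,Con-anc-N/C/L5/L6/L3,1.9,7.6,0.71
23,Con-anc-N/C/L5/L6/L3,-,-,-
41,Con-anc-N/C/L5/L6/L3,1.0,7.7,0.96
42,Con-anc-N/C/L5/L6/L3,0.40,6.4,0.76
43,Con-anc-N/C/L5/L6/L3,0.35,5.5,0.99
26,Con-anc-N/C/L5/L6/L3,4.8,5.5,1.42
27,Con-anc-N/C/L5/L6/L3,-,-,-
28,Con-anc-N/C/L5/L6/L3,5.2,8.8,0.53
29,Con-anc-N/C/L5/L6/L3,-,-,-
30,Con-anc-N/C/L5/L6/L3,-,-,-
31,Con-anc-N/C/L5/L6/L3,-,-,-
32,Con-anc-N/C/L5/L6/L3,7,5.6,0.68
33,Con-anc-N/C/L5/L6/L3,-,-,-
34,Con-anc-N/C/L5/L6/L3,9,5.7,0.75
38,Con-anc-N/C/L5/L6/L3,-,-,-
39,Con-anc-N/C/L5/L6/L3,4,15,0.64
40,Con-anc-N/C/L5/L6/L3,238,0.27,-
44,Con-anc-N/C/L5/L6/L3,3.0,19,1.49
45,Con-anc-N/C/L5/L6/L3,15,11,0.87
46,Con-anc-N/C/L5/L6/L3,6.0,7.3,1.57
47,Con-anc-N/C/L5/L6/L3,3.0,11,1.30
48,Con-anc-N/C/L5/L6/L3,8.1,6.9,2.08
49,Con-anc-N/C/L5/L6/L3,8.7,7.2,1.16
50,Con-anc-N/C/L5/L6/L3,-,-,-
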