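area_px,major_axis_px,minor_axis_px,label
89,14.245,8.04,single
49,10.355,6.149,single
43,10.014,5.601,single
61,12.477,6.343,single
59,12.827,5.999,single
66,11.764,7.251,single
60,15.439,5.074,single
72,11.721,7.904,single
73,14.512,6.506,single
48,12.248,5.085,single
99,15.944,8.004,single
75,12.632,7.675,single
71,15.168,6.059,single
65,10.381,8.077,single
72,13.889,6.717,single
84,13.225,8.151,single
78,15.802,6.37,single
68,10.759,8.152,single
94,15.853,7.633,single
73,12.785,7.374,single
63,11.205,7.235,single
86,15.405,7.204,single
69,13.902,6.429,single
98,15.418,8.206,single
67,12.939,6.699,single
93,14.64,8.183,single
55,9.606,7.395,single
87,15.208,7.39,single
74,12.969,7.36,single
103,15.749,8.398,single
81,14.988,6.973,single
86,14.734,7.527,single
79,14.559,6.993,single
78,12.225,8.215,single
71,16.442,5.63,single
84,14.476,7.483,single
52,10.406,6.467,single
71,15.6,5.89,single
89,14.234,8.072,single
41,9.3,5.729,single
85,13.17,8.312,single
61,15.619,5.111,single
63,10.88,7.476,single
56,12.294,5.925,single
43,9.94,5.636,single
89,13.655,8.413,single
62,11.432,7.007,single
83,12.597,8.501,single
100,15.469,8.315,single
87,13.667,8.205,single
64,9.936,8.302,single
61,15.68,5.081,single
99,15.93,8.001,single
40,9.825,5.315,single
49,10.608,5.999,single
62,11.868,6.799,single
61,10.105,7.798,single
50,13.05,5.026,single
84,13.55,7.977,single
65,11.045,7.627,single
110,16.544,8.861,multi
113,16.111,10.28,multi
133,17.713,10.848,multi
120,13.815,12.156,multi
110,18.062,8.87,multi
93,15.207,7.864,multi
124,18.86,9.368,multi
120,16.229,10.051,multi
119,21.587,7.957,multi
142,18.12,12.966,multi
147,18.066,12.491,multi
142,17.883,13.336,multi
95,16.067,9.089,multi
66,15.239,5.624,multi
114,17.62,8.518,multi
117,23.619,9.732,multi
90,14.629,9.465,multi
95,12.579,10.262,multi
119,20.247,8.238,multi
125,19.582,8.932,multi
136,18.729,9.802,multi
105,19.004,7.576,multi
131,19.17,8.986,multi
120,19.284,8.764,multi
137,26.281,6.971,multi
130,13.883,12.525,multi
127,18.141,10.289,multi
107,18.21,9.321,multi
104,17.615,7.998,multi
135,18.008,10.043,multi
45,27.96,2.295,noise
53,32.204,2.424,noise
39,22.624,2.467,noise
61,33.356,2.62,noise
55,29.241,2.642,noise
39,26.955,2.168,noise
49,33.921,2.158,noise
37,23.098,2.321,noise
41,26.927,2.242,noise
55,30.896,2.525,noise
53,31.395,2.448,noise
39,25.61,2.197,noise
59,38.751,2.237,noise
51,33.796,2.225,noise
39,27.62,2.126,noise
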