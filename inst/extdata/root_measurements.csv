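root_id,bl_1,bl_2,bl_error,md_1,md_2,md_error,rl_1,rl_2,rl_error
1,9.57,9.95,-0.38,5.82,6.15,-0.33,16.13,14.59,1.54
2,10.4,10.79,-0.39,7.09,7.5,-0.41,9.31,7.74,1.57
3,9.46,9.8,-0.34,9.06,9.55,-0.49,8.96,8.39,0.57
4,9.05,9.54,-0.49,5.37,5.94,-0.57,11.98,12.01,-0.03
5,8.86,9.38,-0.52,5.43,5.84,-0.41,12.32,11.76,0.56
6,8.3,8.77,-0.47,5.01,4.94,0.07,12.07,11.62,0.45
7,8.2,8.84,-0.64,4.65,5.09,-0.44,13.3,13.15,0.15
8,9.2,9.41,-0.21,5.68,5.53,0.15,13.98,13.85,0.13
9,9.9,10.07,-0.17,6.1,6.11,-0.01,12.85,12.27,0.58
10,9.59,9.84,-0.25,5.86,5.88,-0.02,13.34,13.26,0.08
11,10.23,10.88,-0.65,6.04,6.52,-0.48,8.47,7.8,0.67
12,8.81,9.32,-0.51,5.59,5.58,0.01,13.99,13.64,0.35
13,8.53,8.83,-0.3,5.38,5.44,-0.06,15.16,14.83,0.33
14,8.63,8.87,-0.24,5.58,5.39,0.19,15.21,14.81,0.4
15,7.16,7.06,0.1,5.67,6.07,-0.4,13.72,13.48,0.24
16,8.81,9.32,-0.51,5.59,5.58,0.01,12.08,11.63,0.45
17,8.53,8.83,-0.3,5.38,5.44,-0.06,14.15,13.71,0.44
18,8.63,8.87,-0.24,5.58,5.39,0.19,14.19,13.73,0.46
19,8.02,8.31,-0.29,5.29,5.43,-0.14,11.51,11.15,0.36
20,9.1,9.31,-0.21,5.88,6.03,-0.15,9.57,9.33,0.24
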