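k	count
63	1
53	2
51	2
46	1
45	1
44	1
43	1
40	2
39	2
38	1
37	2
36	3
34	1
32	3
31	15
30	3
29	8
28	1
27	1
26	2
25	1
24	1
22	4
21	1
20	2
19	1
17	1
16	2
15	2
13	4
12	1
11	2
10	1
9	1
8	2
7	5
6	3
4	1
3	3
0	27
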