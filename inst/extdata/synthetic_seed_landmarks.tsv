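column_index	element
1	b2
2	b2
3	b2
4	b2
5	b2
6	b2
7	L23
8	L23
9	L23
10	L23
11	b3
12	b3
13	b3
14	b3
15	b3
16	b3
17	L34
18	L34
19	L34
20	L34
21	L34
22	L34
23	L34
24	L34
25	b4
26	b4
27	b4
28	b4
29	b4
30	b4
31	b4
32	L45
33	L45
34	b5
35	b5
36	b5
37	b5
38	b5
39	L57
40	L57
41	L57
42	L57
43	L57
44	L57
45	L57
46	L57
47	L57
48	L57
49	L57
50	L57
51	L57
52	L57
53	b7
54	b7
55	b7
56	b7
57	b7
58	b7
59	b7
60	L78
61	L78
62	L78
63	L78
64	L78
65	b8
66	b8
67	b8
68	b8
69	b8
70	b8
71	b8
72	L89
73	L89
74	L89
75	L89
76	b9
77	b9
78	b9
79	b9
80	b9
81	b9
82	b9
83	b9
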