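sample_id	score	group
1	0.6863	g1
2	0.9162	g1
3	0.5702	g1
4	0.3088	g2
5	0.1045	g1
6	0.6186	g1
7	0.4653	g1
8	0.663	g1
9	0.0649	g2
10	0.4488	g1
11	0.4756	g1
12	0.5259	g1
13	0.3854	g2
14	0.4988	g1
15	0.8191	g1
16	-0.7887	g2
17	-1.4609	g2
18	-0.9705	g2
19	0.4219	g2
20	-0.9886	g2
21	-0.4688	g2
22	-1.1119	g2
23	-0.8376	g1
24	-0.7741	g2
25	-1.0691	g2
26	-0.213	g2
27	-0.7735	g1
28	-0.2913	g1
29	-1.137	g2
30	-0.1975	g1
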