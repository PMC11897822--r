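f1	f2	f3	f4	f5	f6	f7	f8	f9	f10	f11	f12	label
1.35	0.5832	0.8279	-0.8332	-0.2183	0.4243	1.8987	-0.5375	0.2672	-0.2771	-0.8416	-0.3045	1
1.3415	0.3456	-0.466	1.6201	-0.124	-0.5113	-0.6117	-0.3255	0.8788	0.7603	-1.0016	1.2893	1
1.5581	2.2278	0.4832	-0.9071	0.2569	-0.6834	-0.1031	-1.3144	1.5912	1.8151	-1.1409	-0.0369	1
1.5249	0.9475	1.8761	0.2037	-0.3655	-0.9208	0.8875	0.5225	-0.8183	-0.0113	0.062	-1.3838	1
1.7412	0.8745	0.5949	-0.1267	-1.9366	-0.9994	-0.2471	-0.5978	-0.9483	1.1813	0.0714	1.0827	1
-1.2852	1.461	-1.1045	-0.5497	0.6152	-1.7172	1.0461	-2.0149	0.5168	0.7982	1.4466	0.9	1
-0.9752	2.5679	2.6752	0.2524	-1.5639	-2.6348	-0.9065	-0.0867	0.9157	0.777	-1.0237	0.6531	1
0.9097	0.7354	2.2532	-0.8002	0.6003	0.9001	1.1621	0.2823	-0.2106	0.3578	-0.3533	-0.2621	1
0.6752	1.7744	0.9632	-0.1084	1.446	1.5385	0.5782	-0.6296	0.42	2.8769	0.6299	-0.0096	1
0.6374	0.3209	0.725	0.7334	-0.8624	-1.7387	-0.2648	1.2758	-0.6216	0.5928	-0.685	2.2457	1
2.3297	-0.6732	0.6139	0.9207	-0.6292	2.0242	-0.2424	-1.7839	-1.3237	-0.2957	0.7434	-1.8466	1
0.8303	1.3288	1.5627	2.3404	1.4514	1.1654	-0.0681	-0.1844	-1.7702	0.1071	-0.1534	1.9832	1
1.3626	1.253	0.9494	-0.7558	1.0599	-0.9056	0.0926	-0.9155	0.1936	-1.238	1.2241	-0.7318	1
2.9355	2.5919	0.9995	1.6781	-0.3354	0.8824	0.1104	-0.8402	0.702	2.2401	-0.8375	0.3997	1
1.6004	2.0179	2.1423	1.3618	0.6346	-0.3097	1.123	-0.7187	-0.0499	0.1921	1.5041	-0.517	1
-1.6512	-2.2035	-0.5596	-0.5619	-0.3343	-0.9936	-0.4542	-1.927	0.0155	-2.5849	0.9936	0.1212	2
-0.819	-3.6899	1.1487	0.5564	1.0801	-1.3953	1.6607	-0.0638	1.0705	-0.2318	-0.3112	0.9434	2
-1.7588	-1.7018	0.0184	0.3893	-0.0379	-0.405	0.7852	-0.5804	-0.1265	1.3934	0.1843	-0.0455	2
-1.9245	-0.7268	-1.7658	-0.4613	-1.6461	0.8272	1.1945	1.6492	1.1758	-0.006	-0.7934	-0.5087	2
-0.4706	0.9221	0.5877	0.4543	2.5051	-1.1552	2.2174	1.0265	-1.1577	-0.9216	-0.9634	-0.5819	2
-0.8399	1.762	-0.8432	0.188	-0.8225	-0.057	-1.7277	-0.899	-0.1176	-1.6342	0.1848	0.3807	2
-2.4028	-2.3355	-0.3823	-0.7195	0.3613	-1.6662	0.2322	0.6726	-1.1817	1.9042	-2.5221	-0.549	2
-0.3215	-2.1979	-2.7284	-0.0689	-0.3247	-0.2805	-1.7579	0.3551	-0.6165	0.8104	-2.4668	-0.3742	2
-2.5729	-1.3325	0.722	-2.4456	0.4642	1.4095	-0.3389	-0.901	0.149	0.4487	0.4577	1.0247	2
-1.36	-1.1924	-0.0548	0.7366	0.2026	-0.0635	-0.966	-0.6566	-0.5182	0.1673	1.0702	0.1325	2
-0.8869	-2.3461	0.1495	-0.1571	0.7664	-0.9754	1.5935	-0.2114	0.1722	-0.1772	-0.2583	0.8371	2
-0.3956	0.3026	0.3104	1.538	0.0139	0.325	1.0766	-0.6197	0.459	-1.8383	-1.1064	0.8801	2
-1.308	-1.5397	-2.2137	1.0824	0.8691	0.4943	0.1093	0.1403	0.1511	0.1994	0.5815	1.0632	2
-0.4077	-1.7071	-0.5418	0.2542	-0.0581	-0.8996	0.8158	0.833	0.383	-1.1783	-0.5467	-0.1366	2
-0.5961	1.0089	-0.5766	1.0724	-1.1021	0.9015	0.1885	-0.4555	1.5892	0.0354	-0.0932	-0.3888	2
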