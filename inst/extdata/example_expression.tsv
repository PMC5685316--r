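gene_id	S001	S002	S003	S004	S005	S006	S007	S008	S009	S010	S011	S012
G00001	1967.834	786.381	3918.805	991.346	1360.569	1250.186	803.495	1321.875	1955.873	3307.587	1088.464	1898.921
G00002	242.288	111.959	52.258	109.845	286.495	16.678	99.855	42.535	58.019	40.728	31.422	154.996
G00003	771.344	2966.908	4222.198	5122.403	580.295	1140.73	905.485	4082.015	1017.64	1814.41	1351.653	701.682
G00004	189.558	390.19	458.602	187.46	244.79	279.159	266.874	235.597	265.586	472.772	206.949	839.063
G00005	941.138	792.007	2448.324	1132.077	655.082	243.958	1011.646	521.77	562.809	1211.879	370.875	1549.001
G00006	64.969	107.437	406.224	177.556	88.697	417.489	240.37	155.979	255.222	441.559	303.369	74.492
G00007	132.949	347.432	104.431	104.485	257.382	233.576	54.582	202.825	365.539	340.682	150.432	92.083
G00008	118.252	69.908	294.366	211.102	122.141	253.754	103.45	170.155	213.601	113.064	74.218	228.662
G00009	2019.853	1312.294	3578.927	5530.998	3326.379	1158.115	1428.493	1863.432	1095.869	3143.126	1361.227	1253.204
G00010	71.302	197.394	147.322	47.985	43.625	70.493	149.581	98.069	108.601	85.576	102.097	80.778
G00011	241.104	301.244	41.389	201.928	169.036	292.067	123.858	132.532	103.167	92.684	423.226	362.713
G00012	757.466	968.383	1539.9	1179.622	2219.908	1339.58	281.426	1206.313	3075.622	1077.28	2081.346	2958.718
G00013	382.051	176.019	215.953	219.063	168.16	175.459	267.804	301.932	299.256	155.15	261.207	283.403
G00014	1920.424	2065.664	1817.825	4881.806	3018.6	1676.27	817.488	2424.246	5693.968	1330.237	1092.891	2285.911
G00015	149.096	62.646	55.836	34.275	131.922	84.064	83.136	102.954	70.959	180.98	79.848	83.638
G00016	156.268	106.492	126.315	267.843	121.126	599.717	568.063	136.335	264.837	354.279	322.529	384.479
G00017	612.542	739.982	190.421	207.23	104.318	123.95	284.685	392.907	317.97	63.22	92.364	364.275
G00018	181.483	65.059	42.201	55.568	133.506	144.054	106.758	144.88	147.739	142.031	292.246	64.136
G00019	185.325	96.559	253.707	214.561	186.578	656.71	1172.403	246.686	226.385	266.772	86.735	148.742
G00020	303.265	157.081	924.548	377.406	805.185	314.253	604.505	965.727	488.886	465.952	184.809	710.904
G00021	44.891	109.091	86.356	86.991	15.104	51.693	132.279	197.049	146.975	38.142	67.856	72.41
G00022	3603.275	4488.293	13480.238	8367.886	2485.739	12496.321	6825.541	9067.846	7308.794	11671.57	6894.867	1154.695
G00023	4482.856	1339.154	2706.917	1594.566	2662.212	1362.863	2746.501	2726.042	3881.605	795.594	3243.632	5937.015
G00024	6978.662	4339.186	9355.769	5723.364	7749.557	3924.381	3002.023	1860.881	2810.373	7606.306	4824.843	1673.364
G00025	116.617	47.199	124.861	55.37	200.943	84.009	122.845	99.372	166.52	324.337	29.701	171.555
G00026	83.225	70.813	94.822	74.654	85.061	201.735	55.754	155.081	91.085	95.309	123.059	28.633
G00027	74.633	90.692	357.808	188.334	62.794	69.305	87.437	193.26	97.037	50.593	127.179	33.274
G00028	279.689	646.544	321.508	128.689	267.645	422.067	278.139	427.25	469.334	153.421	157.48	689.624
G00029	635.055	504.546	1153.683	1286.107	346.84	3334.287	770.205	804.583	693.852	1218.102	1510.569	166.87
G00030	7435.842	2392.987	2321.768	3219.249	1269.731	2441.182	3260.562	2319.529	3637.938	1405.969	1875.468	1645.224
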