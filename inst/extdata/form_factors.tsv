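element	a1	b1	a2	b2	a3	b3	a4	b4	c
H	0.489918	20.6593	0.262003	7.74039	0.196767	49.5519	0.049879	2.20159	0.001305
C	2.31	20.8439	1.02	10.2075	1.5886	0.5687	0.865	51.6512	0.2156
N	12.2126	0.0057	3.1322	9.8933	2.0125	28.9975	1.1663	0.5826	-11.529
O	3.0485	13.2771	2.2868	5.7011	1.5463	0.3239	0.867	32.9089	0.2508
F	3.5392	10.2825	2.6412	4.2944	1.517	0.2615	1.0243	26.1476	0.2776
Si	6.2915	2.4386	3.0353	32.3337	1.9891	0.6785	1.541	81.6937	1.1407
P	6.4345	1.9067	4.1791	27.157	1.78	0.526	1.4908	68.1645	1.1149
S	6.9053	1.4679	5.2034	22.2151	1.4379	0.2536	1.5863	56.172	0.8669
Cl	11.4604	0.0104	7.1964	1.1662	6.2556	18.5194	1.6455	47.7784	-9.5574
Br	17.1789	2.1723	5.2358	16.5796	5.6377	0.2609	3.9851	41.4328	2.9557
Sc	9.189	9.0213	7.3679	0.5729	1.6409	136.108	1.468	51.3531	1.3329
Ti	9.7595	7.8508	7.3558	0.5	1.6991	35.6338	1.9021	116.105	1.2807
V	10.2971	6.8657	7.3511	0.4385	2.0703	26.8938	2.0571	102.478	1.2199
Cr	10.6406	6.1038	7.3537	0.392	3.324	20.2626	1.4922	98.7399	1.1832
Mn	11.2819	5.3409	7.3573	0.3432	3.0193	17.8674	2.2441	83.7543	1.0896
Fe	11.7695	4.7611	7.3573	0.3072	3.5222	15.3535	2.3045	76.8805	1.0369
Co	12.2841	4.2791	7.3409	0.2784	4.0034	13.5359	2.3488	71.1692	1.0118
Ni	12.8376	3.8785	7.292	0.2565	4.4438	12.1763	2.38	66.3421	1.0341
Cu	13.338	3.5828	7.1676	0.247	5.6158	11.3966	1.6735	64.8126	1.191
Zn	14.0743	3.2655	7.0318	0.2333	5.1652	10.3163	2.41	58.7097	1.3041
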