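label,ac,entry,description,score,match,tp,dp,theor_mw_kda,theor_pi,exp_mw_kda,exp_pi,fc
1a,P00450,CERU_HUMAN,Ceruloplasmin,100,20,107,21,122.128,5.44,155.47,5.00,-1.57
1b,,,,100,12,,13,,,137.48,4.93,-2.11
2,P01024,CO3_HUMAN,Complement C3,99.95,11,196,21,187.030,6.02,138.40,5.40,-1.05
3a,P01024,CO3_HUMAN,Complement C3,100,15,196,29,187.030,6.02,77.14,6.51,1.29
3b,,,,98.66,14,,28,,,76.93,6.38,1.05
4,Q14624,ITIH4_HUMAN,Inter-alpha-trypsin inhibitor heavy chain H4,100,18,98,18,103.293,6.51,132.41,4.83,-5.11
5,P05155,IC1_HUMAN,Plasma protease C1 inhibitor,100,7,44,3,55.119,6.09,110.98,4.16,-2.93
6a,P06396,GELS_HUMAN,Gelsolin,100,13,88,11,85.644,5.9,100.95,5.49,1.08
6b,,,,94.55,2,,2,,,100.68,5.41,-1.12
6c,,,,100,8,,7,,,100.47,5.35,1.12
7,P00734,THRB_HUMAN,Prothrombin,99.99,5,74,4,69.992,5.64,89.00,4.80,-12.51
8a,P04217,A1BG_HUMAN,Alpha-1B-glycoprotein,100,16,45,7,54.220,5.56,79.91,4.95,-2.36
8b,,,,99.89,11,,5,,,92.19,4.93,-4.39
9a,P02787,TRFE_HUMAN,Serotransferrin,100,22,86,19,77.014,6.81,85.76,3.89,-3.49
9b,,,,100,13,,11,,,85.99,4.00,-1.85
9c,,,,99.99,17,,15,,,86.26,4.13,-2.53
9d,,,,99.99,20,,17,,,85.52,4.42,-3.20
9e,,,,100,19,,16,,,86.63,5.88,2.28
9f,,,,100,23,,20,,,85.03,5.94,3.04
9g,,,,100,14,,12,,,82.63,6.01,2.41
9h,,,,100,15,,13,,,82.25,6.11,1.59
9i,,,,100,23,,20,,,83.99,6.25,1.11
9j,,,,100,5,,4,,,84.30,6.39,-1.01
9k,,,,100,19,,16,,,84.56,7.03,2.99
10a,P02768,ALBU_HUMAN,Serum albumin,100,24,88,21,69.321,5.92,70.29,5.59,5.45
10b,,,,100,19,,17,,,75.28,5.38,-1.37
11,P02768,ALBU_HUMAN,Serum albumin,100,15,88,13,69.321,5.92,64.25,6.26,1.09
12,P02748,CO9_HUMAN,Complement component C9,100,17,70,12,63.133,5.43,72.20,4.94,-3.02
13,P01876,IGHA1_HUMAN,Ig alpha-1 chain C region,99.96,23,26,6,37.631,6.08,64.70,5.26,-1.32
14,P01011,AACT_HUMAN,Alpha-1-antichymotrypsin,100,26,43,11,47.621,5.33,63.68,4.43,-2.11
15a,P01009,A1AT_HUMAN,Alpha-1-antitrypsin,100,46,41,19,46.707,5.37,65.21,4.97,-2.11
15b,,,,100,54,,22,,,68.91,4.74,-4.52
15c,,,,100,17,,7,,,55.64,4.82,-3.24
15d,,,,94.67,29,,12,,,59.76,5.88,2.12
16,P01009,A1AT_HUMAN,Alpha-1-antitrypsin,100,39,41,16,46.707,5.37,139.43,4.82,-5.12
17,P02765,FETUA_HUMAN,Alpha-2-HS-glycoprotein,94.42,21,29,6,39.300,5.43,54.46,4.47,-2.18
18a,P01859,IGHG2_HUMAN,Ig gamma-2 chain C region,99.49,19,32,6,35.878,7.66,54.11,6.12,2.05
18b,,,,99.31,16,,5,,,53.51,6.22,1.45
18c,,,,99.49,19,,6,,,53.38,6.30,1.19
19,P01860,IGHG3_HUMAN,Ig gamma-3 chain C region,99.5,3,40,1,41.260,8.23,52.99,6.67,-1.08
20a,P51884,LUM_HUMAN,Lumican,100,23,35,8,38.405,6.16,50.27,5.26,-1.80
20b,,,,100,17,,6,,,50.64,5.16,-2.26
21,P02763,A1AG1_HUMAN,Alpha-1-acid glycoprotein 1,100,13,23,3,23.497,4.93,46.02,4.10,-1.39
22a,P25311,ZA2G_HUMAN,Zinc-alpha-2-glycoprotein,100,41,34,14,34.237,5.71,41.51,4.68,-4.38
22b,,,,98.89,32,,11,,,39.71,4.79,-4.48
23,P00738,HPT_HUMAN,Haptoglobin,45.47,18,45,8,45.177,6.13,39.41,4.86,-3.54
24a,P01857,IGHG1_HUMAN,Ig gamma-1 chain C region,99.98,18,34,6,36.083,8.46,37.54,6.67,1.86
24b,,,,34.45,9,,3,,,37.01,6.80,-1.63
25a,P01857,IGHG1_HUMAN,Ig gamma-1 chain C region,100,24,34,8,36.083,8.46,53.65,6.93,1.14
25b,,,,100,21,,7,,,53.23,7.30,-1.13
26,P0C0L5,CO4B_HUMAN,Complement C4-B,99.36,6,187,12,192.631,6.89,29.70,6.29,1.25
27,P08833,IBP1_HUMAN,Insulin-like growth factor-binding protein 1,99.97,24,21,5,27.885,5.11,28.94,4.80,-3.41
28,P02760,AMBP_HUMAN,Protein AMBP,100,8,38,3,38.974,5.95,28.51,4.89,-1.41
29,A0M8Q6,LAC7_HUMAN,Ig lambda-7 chain C region,99.45,25,12,3,11.296,8.49,25.21,6.67,1.07
30a,P01834,IGKC_HUMAN,Ig kappa chain C region,54.8,27,11,3,11.602,5.58,23.89,5.77,3.89
30b,,,,54.65,27,,3,,,23.47,6.03,2.58
30c,,,,96.48,18,,2,,,23.32,6.18,1.71
30d,,,,99.66,27,,3,,,23.30,6.56,1.27
30e,,,,99.93,18,,2,,,23.43,6.81,1.33
31,P01622,KV304_HUMAN,Ig kappa chain V-III region Ti,54.65,20,10,2,11.781,8.72,23.39,7.02,-1.38
32,P98160,PGBM_HUMAN,Basement membrane-specific heparan sulfate proteoglycan core protein,100,2,329,8,468.532,6.06,20.25,5.37,-2.76
33a,P02766,TTHY_HUMAN,Transthyretin,100,21,14,3,15.877,5.52,14.10,5.21,-2.08
33b,,,,47.6,36,,5,,,14.22,5.00,-2.48
34a,P02766,TTHY_HUMAN,Transthyretin,100,57,14,8,15.877,5.52,32.99,5.24,-1.82
34b,,,,43.3,36,,5,,,31.48,5.01,-2.61
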