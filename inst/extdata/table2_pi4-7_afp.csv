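label,ac,entry,description,score,match,tp,dp,theor_mw_kda,theor_pi,exp_mw_kda,exp_pi,share_pct
1A,P00450,CERU_HUMAN,Ceruloplasmin,100,7,107,6,122.128,5.44,125.413,5.11,13.8
1B,,,,38.76,13,,11,,,124.394,5.2,15.9
1C,,,,100,7,,6,,,160.438,5.22,70.3
8A,P04217,A1BG_HUMAN,Alpha-1B-glycoprotein,95.3,20,45,7,54.220,5.56,78.913,5.1,30.7
8B,,,,100,31,,11,,,73.612,5.19,23.6
8C,,,,91.35,20,,8,,,73.460,5.22,45.7
9A,P02787,TRFE_HUMAN,Serotransferrin,100,24,86,17,77.014,6.81,82.460,4.72,27.6
9B,,,,99.99,21,,16,,,82.617,4.85,5.0
9C,,,,99.99,17,,13,,,82.309,4.97,7.2
9D,,,,100,20,,13,,,82.416,5.04,13.1
9E,,,,92.46,15,,11,,,81.032,6.1,12.3
9F,,,,100,16,,12,,,87.691,6.33,5.1
9G,,,,100,23,,17,,,86.703,6.37,7.7
9H,,,,100,25,,17,,,86.995,6.46,7.5
9I,,,,100,24,,16,,,87.640,6.51,6.4
9J,,,,99.99,22,,16,,,88.003,6.6,8.0
10A,P02768,ALBU_HUMAN,Serum albumin,100,26,88,17,69.321,5.92,68.406,4.63,82.4
10B,,,,99.81,15,,10,,,66.982,5.83,4.6
10C,,,,99.75,19,,13,,,66.903,5.87,8.3
10D,,,,97.61,24,,14,,,66.783,5.96,4.7
12,P02748,CO9_HUMAN,Complement component C9,99.64,21,70,12,63.133,5.43,67.943,5.18,
14A,P01011,AACT_HUMAN,Alpha-1-antichymotrypsin,99.99,36,43,12,47.621,5.33,63.391,4.42,28.4
14B,,,,100,37,,13,,,64.130,4.4,21.1
14C,,,,100,40,,14,,,64.980,4.37,31.8
14D,,,,100,36,,12,,,65.103,4.32,18.7
15A,P01009,A1AT_HUMAN,Alpha-1-antitrypsin,95.46,25,41,12,46.707,5.37,52.167,4.81,2.8
15B,,,,100,36,,15,,,52.340,4.9,5.3
15C,,,,99.48,34,,13,,,51.942,4.98,1.9
15D,,,,100,43,,20,,,55.594,5.12,16.9
15E,,,,100,43,,18,,,56.410,5.06,10.0
15F,,,,100,16,,8,,,57.418,5.04,16.4
15G,,,,100,45,,16,,,58.708,5.02,19.8
15H,,,,100,51,,21,,,57.694,4.99,10.5
15I,,,,100,53,,22,,,58.746,4.93,8.3
15J,,,,100,38,,15,,,54.340,4.87,8.0
16A,P01009,A1AT_HUMAN,Alpha-1-antitrypsin,99.99,35,41,15,46.707,5.37,125.779,4.98,65.1
16B,,,,77.76,36,41,14,,,124.943,5.05,34.9
17A,P02765,FETUA_HUMAN,Alpha-2-HS-glycoprotein,99.4,15,29,4,39.300,5.43,57.132,4.31,28.2
17B,,,,99.99,13,,3,,,57.942,4.39,19.9
17C,,,,98.94,14,,4,,,57.136,4.43,18.9
17D,,,,99.33,15,,4,,,57.461,4.51,15.8
17E,,,,100,15,,4,,,56.984,4.58,17.2
18,P01859,IGHG2_HUMAN,Ig gamma-2 chain C region,99.86,14,32,5,35.878,7.66,246.031,6.62,
20,P51884,LUM_HUMAN,Lumican,99.99,15,35,6,38.405,6.16,51.234,4.69,
21,P02763,A1AG1_HUMAN,Alpha-1-acid glycoprotein 1,97.2,17,23,4,23.497,4.93,48.113,4.16,
22A,P25311,ZA2G_HUMAN,Zinc-alpha-2-glycoprotein,100,35,34,12,34.237,5.71,42.866,4.92,40.5
22B,,,,99.99,26,,9,,,42.745,5.02,59.5
23A,P00738,HPT_HUMAN,Haptoglobin,95.86,18,45,8,45.177,6.13,44.988,4.97,68.2
23B,,,,95.86,18,45,8,,,43.946,5.11,31.8
24A,P01857,IGHG1_HUMAN,Ig gamma-1 chain C region,100,12,34,3,36.083,8.46,58.164,6.82,33.7
24B,,,,100,41,,10,,,57.942,6.75,66.3
27A,P08833,IBP1_HUMAN,Insulin-like growth factor-binding protein 1,75.3,29,21,6,27.885,5.11,31.024,5.07,55.4
27B,,,,24.73,19,,4,,,30.460,5.3,44.6
28A,P02760,AMBP_HUMAN,Protein AMBP,98.5,8,38,3,38.974,5.95,30.648,4.9,22.4
28B,,,,98.06,11,,4,,,30.712,5.02,46.0
28C,,,,100,21,,8,,,29.843,5.17,31.5
30A,P01834,IGKC_HUMAN,Ig kappa chain C region,76.74,18,11,2,11.602,5.58,24.106,5.59,18.3
30B,,,,92.81,18,,2,,,25.013,5.9,6.9
30C,,,,73.4,45,,5,,,25.647,6.01,7.1
30D,,,,99.97,36,,4,,,25.687,6.32,8.2
30E,,,,95.96,36,,4,,,25.946,6.49,4.5
30F,,,,54.8,27,,3,,,26.768,6.7,24.8
30G,,,,85.98,18,,2,,,26.416,6.9,30.3
32A,P98160,PGBM_HUMAN,Basement membrane-specific heparan sulfate proteoglycan core protein,97.93,3,329,9,468.532,6.06,21.035,5.59,57.8
32B,,,,100,5,,15,,,21.546,5.82,42.2
33A,P02766,TTHY_HUMAN,Transthyretin,100,36,14,5,15.877,5.52,13.645,5.38,51.0
33B,,,,100,50,,7,,,13.681,5.68,49.0
34,P02766,TTHY_HUMAN,Transthyretin,100,36,14,5,15.877,5.52,34.100,5.63,
35,P02751,FINC_HUMAN,Fibronectin,34.38,16,204,28,262.460,5.46,281.640,5.43,
36,P00450,CERU_HUMAN,Ceruloplasmin,98.8,19,107,16,122.128,5.44,301.394,5.17,
37A,P02787,TRFE_HUMAN,Serotransferrin,99.95,17,86,12,77.014,6.81,282.942,6.31,35.9
37B,,,,99.95,17,,12,,,279.480,6.38,32.5
37C,,,,99.99,17,,7,,,280.342,6.44,31.5
38,P02768,ALBU_HUMAN,Serum albumin,89.83,24,88,14,69.321,5.92,250.992,5.88,
39A,P01008,ANT3_HUMAN,Antithrombin-III,90.29,33,60,13,52.569,6.32,58.761,5.43,18.5
39B,,,,100,31,,12,,,60.463,5.38,13.7
39C,,,,100,38,,16,,,59.465,5.34,67.8
40,P01008,ANT3_HUMAN,Antithrombin-III,100,36,60,17,52.569,6.32,246.108,5.18,
41,P43652,AFAM_HUMAN,Afamin,90.07,22,76,14,69.024,5.64,95.405,5.08,
42,P01009,A1AT_HUMAN,Alpha-1-antitrypsin,100,17,41,7,46.707,5.37,232.691,5.03,
43A,P02790,HEMO_HUMAN,Hemopexin,100,24,46,10,51.643,6.55,68.403,5.31,47.2
43B,,,,98.19,16,,6,,,69.730,5.52,52.8
44A,P01042,KNG1_HUMAN,Kininogen-1,100,15,73,10,71.912,6.34,60.418,4.62,24.2
44B,,,,100,16,,9,,,61.470,4.57,28.5
44C,,,,100,13,,8,,,63.011,4.51,36.8
44D,,,,100,9,,6,,,59.137,4.64,10.5
45,P02749,APOH_HUMAN,Beta-2-glycoprotein 1,19.26,8,41,3,38.273,8.34,60.134,6.33,
46,P01019,ANGT_HUMAN,Angiotensinogen,71.35,22,39,7,53.121,5.87,55.993,5.37,
47A,P02750,A2GL_HUMAN,Leucine-rich alpha-2-glycoprotein,99.85,13,32,4,38.154,6.45,50.640,4.41,56.3
47B,,,,99.85,13,,4,,,48.940,4.52,43.7
48,P63261,ACTG_HUMAN,Actin. cytoplasmic 2,81.07,17,38,5,41.766,5.31,44.097,5.32,
49,P10909,CLUS_HUMAN,Clusterin,76.74,7,59,4,52.461,5.89,37.061,4.78,
50,P02452,CO1A1_HUMAN,Collagen alpha-1(I) chain,99.7,3,129,4,138.857,5.6,32.106,5.25,
51,P08123,CO1A2_HUMAN,Collagen alpha-2(I) chain,99.98,5,122,6,129.235,9.08,29.514,6.02,
52,P18136,KV313_HUMAN,Ig kappa chain V-III region HIC,91.75,20,10,2,14.080,6.18,26.543,6.57,
53,P02753,RET4_HUMAN,Retinol-binding protein 4,49.11,22,27,6,22.995,5.76,21.842,5.37,
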