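"age_years","weekly_mortality_probability"
0,1.03746652690972e-05
1,1.04433901950696e-05
2,1.05183352528959e-05
3,1.060006341147e-05
4,1.06891885928162e-05
5,1.07863802831787e-05
6,1.08923685623319e-05
7,1.1007949587527e-05
8,1.11339915739306e-05
9,1.12714413167403e-05
10,1.14213313026079e-05
11,1.15847874655461e-05
12,1.17630376447186e-05
13,1.19574208072848e-05
14,1.21693971061321e-05
15,1.24005588478804e-05
16,1.26526424538698e-05
17,1.29275415030605e-05
18,1.32273209557665e-05
19,1.3554232664581e-05
20,1.39107322891796e-05
21,1.42994977415656e-05
22,1.47234493013126e-05
23,1.51857715505743e-05
24,1.56899372947272e-05
25,1.62397336476161e-05
26,1.68392904772441e-05
27,1.74931114264032e-05
28,1.82061077399487e-05
29,1.89836351537354e-05
30,1.98315341217725e-05
31,2.07561736833561e-05
32,2.17644993006916e-05
33,2.28640850244988e-05
34,2.40631903808408e-05
35,2.53708224051685e-05
36,2.67968032902077e-05
37,2.8351844153951e-05
38,3.00476254840865e-05
39,3.18968848596057e-05
40,3.39135126101731e-05
41,3.61126561303493e-05
42,3.85108336314888e-05
43,4.11260581850703e-05
44,4.39779729870526e-05
45,4.7087998860218e-05
46,5.04794950981768e-05
47,5.41779348595117e-05
48,5.82110964256755e-05
49,6.26092717583848e-05
50,6.74054939177049e-05
51,7.2635785047348e-05
52,7.83394267842574e-05
53,8.45592551188545e-05
54,9.13419819132955e-05
55,9.87385454871426e-05
56,0.000106804492893242
57,0.000115600396745075
58,0.000125192309713418
59,0.000135652260092045
60,0.000147058792135168
61,0.00015949755520539
62,0.000173061946130315
63,0.000187853809564098
64,0.000203984201576191
65,0.000221574222161736
66,0.000240755922874314
67,0.000261673296337861
68,0.000284483354997978
69,0.000309357307128
70,0.000336481838822511
71,0.000366060511482469
72,0.000398315285146444
73,0.000433488178935404
74,0.000471843080877443
75,0.000513667720463018
76,0.000559275818455163
77,0.000609009429756613
78,0.000663241496520861
79,0.000722378630194087
80,0.000786864142803823
81,0.000857181349570579
82,0.000933857166826924
83,0.00101746603129149
84,0.00110863416897422
85,0.00120804424439414
86,0.00131644042339141
87,0.00143463388560539
88,0.00156350882570722
89,0.00170402898570277
90,0.00185724476409488
91,0.00202430095140915
92,0.00220644514555668
93,0.00240503690474791
94,0.00262155770017114
95,0.00285762173543724
96,0.00311498770483953
97,0.00339557156780335
98,0.00370146042248276
99,0.00403492756728252
100,0.00439844884511942
101,0.00479472037145368
102,0.00522667775345442
103,0.00569751691405707
104,0.00621071664103223
105,0.00677006298739335
106,0.00737967565539732
107,0.00804403650183705
108,0.00876802030709023
109,0.00955692795417551
110,0.0104165221665681
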