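age,sex,all_cause_q,noncirc_fraction
40,male,0.00136172500558416,0.92
41,male,0.00149444108758633,0.918
42,male,0.00164009190923841,0.916
43,male,0.00179993811271193,0.914
44,male,0.00197536320455199,0.912
45,male,0.00216788553025234,0.91
46,male,0.0023791714158933,0.908
47,male,0.00261104959058648,0.906
48,male,0.00286552701455606,0.904
49,male,0.00314480624985226,0.902
50,male,0.00345130452404477,0.9
51,male,0.00378767465189675,0.898
52,male,0.00415682799610154,0.896
53,male,0.00456195966581254,0.894
54,male,0.00500657617106563,0.892
55,male,0.00549452577244952,0.89
56,male,0.00603003178870764,0.888
57,male,0.00661772915055679,0.886
58,male,0.00726270451710422,0.884
59,male,0.00797054030208054,0.882
60,male,0.00874736299094549,0.88
61,male,0.00959989616706284,0.878
62,male,0.0105355187058982,0.876
63,male,0.0115623286409244,0.874
64,male,0.0126892132540087,0.872
65,male,0.0139259259969311,0.87
66,male,0.0152831709098069,0.868
67,male,0.0167726952670754,0.866
68,male,0.0184073912529273,0.864
69,male,0.0202014075461961,0.862
70,male,0.0221702717805061,0.86
71,male,0.0243310249395992,0.858
72,male,0.0267023688510635,0.856
73,male,0.0293048280550566,0.854
74,male,0.0321609274490351,0.852
75,male,0.035295387246049,0.85
76,male,0.0387353369340079,0.848
77,male,0.0425105500877901,0.846
78,male,0.0466537020665468,0.844
79,male,0.0512006528266326,0.842
80,male,0.0561907572979748,0.84
81,male,0.0616672060102632,0.838
82,male,0.0676773989171577,0.836
83,male,0.0742733556540541,0.834
84,male,0.0815121657802816,0.832
85,male,0.0894564829026874,0.83
86,male,0.0981750669573629,0.828
87,male,0.107743379343087,0.826
88,male,0.118244236057512,0.824
89,male,0.129768524489126,0.822
90,male,0.142415990069015,0.82
91,male,0.156296099591063,0.818
92,male,0.171528988672841,0.816
93,male,0.188246501557675,0.814
94,male,0.206593332257632,0.812
95,male,0.226728276914276,0.81
96,male,0.248825608216684,0.808
97,male,0.273076583772618,0.806
98,male,0.299691101488177,0.804
99,male,0.328899516283617,0.802
100,male,0.360954633869451,0.8
101,male,0.396133898839423,0.798
102,male,0.434741796018824,0.796
103,male,0.477112485852381,0.794
104,male,0.523612696641623,0.792
105,male,0.574644898664715,0.79
106,male,0.630650787651529,0.788
107,male,0.69211510776423,0.786
108,male,0.7,0.784
109,male,0.7,0.782
110,male,0.7,0.78
111,male,0.7,0.778
112,male,0.7,0.776
113,male,0.7,0.774
114,male,0.7,0.772
115,male,0.7,0.77
40,female,0.000774787441141523,0.92
41,female,0.000853707579373065,0.918
42,female,0.000940666552371094,0.916
43,female,0.0010364831988484,0.914
44,female,0.001142059764735,0.912
45,female,0.00125839039906843,0.91
46,female,0.00138657051527863,0.908
47,female,0.00152780710601679,0.906
48,female,0.0016834301086565,0.904
49,female,0.00185490492848911,0.902
50,female,0.00204384623753646,0.9
51,female,0.00225203317891582,0.898
52,female,0.0024814261199271,0.896
53,female,0.00273418511161581,0.894
54,female,0.003012690228634,0.892
55,female,0.00331956398092703,0.89
56,female,0.00365769600828311,0.888
57,female,0.0040302702902789,0.886
58,female,0.00444079512784037,0.884
59,female,0.00489313617873655,0.882
60,female,0.00539155285808114,0.88
61,female,0.00594073844660271,0.878
62,female,0.00654586428435837,0.876
63,female,0.00721262846603554,0.874
64,female,0.00794730949637546,0.872
65,female,0.00875682541095807,0.87
66,female,0.00964879891905222,0.868
67,female,0.0106316291819409,0.866
68,female,0.0117145709026134,0.864
69,female,0.0129078214715634,0.862
70,female,0.0142226169892902,0.86
71,female,0.0156713380696878,0.858
72,female,0.0172676264206074,0.856
73,female,0.0190265132993585,0.854
74,female,0.0209645610527363,0.852
75,female,0.0231000190743685,0.85
76,female,0.0254529956479361,0.848
77,female,0.0280456472944089,0.846
78,female,0.0309023874062604,0.844
79,female,0.0340501161332433,0.842
80,female,0.0375184736844143,0.84
81,female,0.0413401194315988,0.838
82,female,0.0455510394424387,0.836
83,female,0.0501908853388708,0.834
84,female,0.0553033476718575,0.832
85,female,0.0609365673282056,0.83
86,female,0.0671435888434385,0.828
87,female,0.0739828598892866,0.826
88,female,0.0815187816391602,0.824
89,female,0.0898223151940547,0.822
90,female,0.0989716497792253,0.82
91,female,0.109052939003625,0.818
92,female,0.120161112115003,0.816
93,female,0.132400767889754,0.814
94,female,0.145887159574713,0.812
95,female,0.160747280155501,0.81
96,female,0.177121058170702,0.808
97,female,0.195162675332118,0.806
98,female,0.215042018358324,0.804
99,female,0.236946278692519,0.802
100,female,0.261081715168247,0.8
101,female,0.287675596220899,0.798
102,female,0.316978339933607,0.796
103,female,0.349265872069011,0.794
104,female,0.384842224291029,0.792
105,female,0.424042397042454,0.79
106,female,0.467235514036347,0.788
107,female,0.514828298065094,0.786
108,female,0.567268900856675,0.784
109,female,0.625051123041515,0.782
110,female,0.688719063966756,0.78
111,female,0.7,0.778
112,female,0.7,0.776
113,female,0.7,0.774
114,female,0.7,0.772
115,female,0.7,0.77
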