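mat,icc,ci_low,ci_high,ci_low_pg2dp,ci_high_pg2dp
1,-0.00832056195484,-0.60766101905,0.546164923723,-0.61,0.55
2,0.15047657662,-0.298831015805,0.541439120577,-0.3,0.54
3,0.6595447968,-0.267533879694,0.94535759795,-0.27,0.95
4,0.99688484985,0.990517251273,0.998992595893,0.99,1
5,0.803267291048,0.571929769335,0.916827915945,0.57,0.92
6,0.981138033076,0.851331950175,0.994350746141,0.85,0.99
7,0.793960969726,0.230327864583,0.930703055401,0.23,0.93
8,0.986487188658,0.148056778413,0.997474915909,0.15,1
9,0.216980992508,-0.226418422927,0.590803828347,-0.23,0.59
10,0.660350309941,0.366420102939,0.834547222839,0.37,0.83
11,0.983372570447,0.908468399014,0.997115246885,0.91,1
12,-0.129796250838,-0.487557454922,0.256566147301,-0.49,0.26
13,0.818207548921,0.500968524158,0.94104284117,0.5,0.94
14,0.000988817193937,-0.474043875108,0.456015076606,-0.47,0.46
15,0.442156246052,-0.0812093973429,0.773631891117,-0.08,0.77
16,0.332523126621,-0.0624241025693,0.655784392872,-0.06,0.66
17,0.377169262155,-0.065586455669,0.716167088019,-0.07,0.72
18,0.693184531017,-0.0711150261632,0.905974462573,-0.07,0.91
19,0.990535110154,0.969822766143,0.996891828007,0.97,1
20,0.171497153438,-0.291938529741,0.631277667913,-0.29,0.63
21,0.977384539619,0.83278888674,0.993444152526,0.83,0.99
22,0.777480489694,0.445318104305,0.922337546754,0.45,0.92
23,0.618299779928,0.333403836742,0.798887508904,0.33,0.8
24,0.0473546696425,-0.607271925444,0.621041347891,-0.61,0.62
25,0.766664467768,0.564548398629,0.882670960441,0.56,0.88
26,0.902495279186,0.754003982818,0.959877573422,0.75,0.96
27,0.48910563329,0.140008799828,0.731880916802,0.14,0.73
28,0.354994325247,-0.096930671007,0.693102326106,-0.1,0.69
29,0.287374486806,-0.10577487838,0.620205725938,-0.11,0.62
30,0.755747111241,0.529982129237,0.881084141405,0.53,0.88
31,0.822692460283,0.626172465145,0.920829632418,0.63,0.92
32,0.298861708081,-0.381118558671,0.818950776912,-0.38,0.82
33,0.0659512394864,-0.297609470919,0.415039751239,-0.3,0.42
34,0.84195344473,0.506219309136,0.957722773304,0.51,0.96
35,0.781184757461,0.324971000295,0.941197381119,0.32,0.94
36,0.542617043252,0.227056511311,0.753797307297,0.23,0.75
37,0.985698906564,0.970428179207,0.993141152894,0.97,0.99
38,0.907280391621,0.712026093412,0.972368702013,0.71,0.97
39,0.985834376071,0.943672555531,0.994806856539,0.94,0.99
40,0.997531714206,0.989677353671,0.999272547968,0.99,1
41,0.552554556518,-0.0664529880377,0.885234247188,-0.07,0.89
42,0.391538605737,-0.339553248134,0.809699884722,-0.34,0.81
43,0.818018334244,0.604982993888,0.921870313008,0.6,0.92
44,0.871062182849,0.725431930853,0.939955741996,0.73,0.94
45,0.566931304097,0.17463291284,0.789787537383,0.17,0.79
46,0.629669582973,0.158976667497,0.865015747298,0.16,0.87
47,0.126555164713,-0.762078495806,0.778064052283,-0.76,0.78
48,-0.0755640160809,-0.397902705543,0.303241712217,-0.4,0.3
49,0.579427520566,-0.690925503123,0.9488184044,-0.69,0.95
50,0.143610006965,-0.349958081017,0.560599426944,-0.35,0.56
51,0.0204219596718,-1.04795705432,0.79281938838,-1.05,0.79
52,0.876772559666,0.289893428756,0.986210485108,0.29,0.99
53,0.668281382377,0.327366409589,0.856763237243,0.33,0.86
54,0.153098533343,-0.371566014626,0.588145925995,-0.37,0.59
55,0.95144685372,0.831728868426,0.983756989145,0.83,0.98
56,0.782092828246,0.0549174878089,0.934151852567,0.05,0.93
57,0.611176467095,-0.135819345668,0.93201548828,-0.14,0.93
58,0.885897446823,0.381852979262,0.98022754151,0.38,0.98
59,0.550858116434,-0.452862253599,0.941415534804,-0.45,0.94
60,0.826993803132,0.565605383477,0.938053669167,0.57,0.94
61,0.936809691076,0.22902546771,0.991999143728,0.23,0.99
62,0.924151508789,0.805937928647,0.971723796681,0.81,0.97
63,0.906086117996,0.566698370183,0.969002454488,0.57,0.97
64,0.950637263702,0.421153537649,0.988428403427,0.42,0.99
65,0.909908739985,0.356353695046,0.976019568131,0.36,0.98
66,-0.345335474143,-0.716160924378,0.386146124526,-0.72,0.39
67,-0.00827825154134,-0.752716140686,0.650261458101,-0.75,0.65
68,0.556359194511,0.12740474502,0.79002133341,0.13,0.79
69,0.672214415368,0.167741001617,0.865214139292,0.17,0.87
70,-0.434178609636,-1.09041265959,0.492561145109,-1.09,0.49
71,0.946423146298,0.797050788619,0.987445439566,0.8,0.99
72,0.94334466617,0.693256335693,0.991723721437,0.69,0.99
73,0.9199127533,0.579460392713,0.988209560967,0.58,0.99
74,-0.260759732873,-0.640487019923,0.197181396355,-0.64,0.2
75,0.371933340351,-0.214566789248,0.775389697627,-0.21,0.78
76,0.623406903704,0.28421167445,0.8263027478,0.28,0.83
77,0.966351818414,0.0324895053232,0.993591000091,0.03,0.99
78,0.440103594,0.0234551761812,0.730583538314,0.02,0.73
79,0.836416404952,0.494692091071,0.956090952166,0.49,0.96
80,0.253425951923,-0.155531169837,0.582763915007,-0.16,0.58
81,0.772484677272,0.16988169653,0.943033884754,0.17,0.94
82,0.365194868286,-0.0496462230171,0.678453824802,-0.05,0.68
83,0.537372761957,0.125642043376,0.788726673282,0.13,0.79
84,0.918858959524,0.644669526293,0.972586986253,0.64,0.97
85,0.396992916021,0.0352933559891,0.671623861297,0.04,0.67
86,0.965093774178,0.92462073195,0.983600281195,0.92,0.98
87,-0.0460969592605,-0.415144962754,0.363167135152,-0.42,0.36
88,-0.172636084432,-0.703179345356,0.404855640094,-0.7,0.4
89,-0.0565980842108,-0.423402482526,0.391878079192,-0.42,0.39
90,0.773942824157,0.494673531826,0.905702322317,0.49,0.91
91,0.934891283687,0.865666058265,0.969197091467,0.87,0.97
92,0.83829077313,0.607337805712,0.938377860671,0.61,0.94
93,0.0873622281973,-0.437772949792,0.562908911496,-0.44,0.56
94,0.914753914292,0.715152029132,0.976351211097,0.72,0.98
95,0.847651916956,0.450575276852,0.96376105926,0.45,0.96
96,0.964795857511,0.849297000571,0.992718324137,0.85,0.99
97,0.554419521617,0.245222881291,0.760530742738,0.25,0.76
98,0.237160351544,-0.164009079792,0.565644338004,-0.16,0.57
99,0.855975685721,0.517796420985,0.960106539224,0.52,0.96
100,0.640248310524,0.338881368907,0.821611791467,0.34,0.82
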