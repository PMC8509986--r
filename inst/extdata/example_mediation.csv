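y,m,delta,exposure,weight
1.492620955956792,482.26408193240957,1,rr,1
1.0981758505340644,362.39069156167983,1,rr,1
2.2319661185346744,60.22746405042405,1,rr,1
4.076366190406735,2762.617180561245,1,Rr,1
3.727868363350767,183.40276107309177,1,rr,1
2.8028924938791464,30.92092616838687,1,rr,1
3.036608797500244,1118.18976077714,1,Rr,1
4.874892689262326,508.38502738870903,1,rr,1
4.474268579190362,32.22525361623996,0,RR,1
4.226341026143373,438.70505573411214,0,RR,1
3.207254572368215,1225.9566481909953,1,Rr,1
4.902205337516561,235.4838741920933,1,Rr,1
3.642668257339299,3086.5039640192367,1,rr,1
2.6510268487391855,217.40226947953616,1,Rr,1
4.789761340423957,62.01520425709707,0,rr,1
4.494213429162088,536.5573605920267,1,rr,1
2.542977939846591,209.2670255724488,1,rr,1
2.9962580436546853,991.3645767276884,1,Rr,1
3.216451301835079,200.03499601382475,1,rr,1
3.995314283042503,231.9538801230679,1,Rr,1
3.8499286457038386,508.3073248059171,1,rr,1
3.7889092511594527,4.658521262152588,0,Rr,1
4.507934988602319,228.44255408323318,1,rr,1
3.667395557472007,315.3563976140698,1,RR,1
3.18815431010935,134.37500438810318,1,Rr,1
4.499272263460422,2234.091551367983,1,Rr,1
3.1791162125291694,1023.6190589807211,1,Rr,1
5.437047165490667,1226.3297089973753,1,Rr,1
3.236450386544329,66.45261950449527,0,rr,1
1.1680973413610216,345.95289533708257,1,Rr,1
3.6639298331491403,185.80804188966272,0,rr,1
4.396808940184937,23.28180311157603,0,Rr,1
4.273596778399766,611.2777229476162,1,Rr,1
1.3729586338562514,352.39671008641915,1,rr,1
4.833848787156893,1709.946045837968,1,Rr,1
4.186914158335556,226.00698896499165,0,rr,1
5.612447801224812,1.1847049998408457,0,Rr,1
4.373433745164724,1102.6287101240282,1,Rr,1
2.5629741847317,15.739145720658588,0,RR,1
4.806141374904958,120.88049660163263,0,rr,1
5.0071812278173855,1601.8352541849035,1,Rr,1
4.94025270159763,2.676585836252892,0,Rr,1
2.931930667665902,247.23133076913112,1,Rr,1
3.3835642448430807,1.3973924657702506,0,RR,1
1.5427160518521372,520.4485207733834,1,Rr,1
1.918944571193881,484.3223844593268,1,rr,1
4.614977688658596,223.81343253963684,1,rr,1
2.861207795062991,141.79351617223622,1,rr,1
4.267234470888445,2228.1238436670405,1,Rr,1
3.4976335512087267,433.74657465426395,1,Rr,1
3.4136401074579896,1065.3410638973937,1,RR,1
5.337861725799498,15.661763650306321,0,Rr,1
4.1155179120723355,242.01726792275093,1,rr,1
4.420763759821212,535.8717705064901,1,RR,1
2.563352818231393,81.34258382404556,1,Rr,1
3.8665732481305444,407.1103319176495,1,rr,1
3.600861833216685,343.3702877952467,1,Rr,1
4.8003135568131245,488.8878177330296,1,Rr,1
5.461800396315885,171.93572402950747,1,Rr,1
3.3718926005254652,312.88292408142604,1,rr,1
5.5727153115983805,1900.3756608254273,1,RR,1
3.7949268683376713,755.1039406184426,1,Rr,1
1.5100458078653727,124.84159491169999,0,Rr,1
5.093331830873882,400.93228401464575,1,rr,1
4.365689931685438,794.9752190472907,1,rr,1
1.9108104359403884,208.31797222638988,1,rr,1
5.66196777966883,1169.8335333107962,1,Rr,1
4.887881411938219,561.0616367815068,1,RR,1
2.8599783365657223,1036.3608640137795,1,Rr,1
3.930453703914292,753.4880489963007,1,Rr,1
3.9194373669657567,207.73650167227336,1,rr,1
3.2098633114760773,972.2038497063197,0,Rr,1
4.875788751274139,452.5509636999647,1,Rr,1
4.376918734677674,3738.045817444349,1,rr,1
5.528990031929853,1009.7193869370165,1,Rr,1
2.1839884966542957,220.79215559710292,1,rr,1
3.2303450468368853,281.93381990669025,1,Rr,1
4.136696554056654,3.584551570928769,0,Rr,1
3.613079180065516,356.31660131679484,1,rr,1
3.1620788512159095,554.0396150232548,0,rr,1
4.737859055413209,1003.2715792675265,1,Rr,1
3.6742808578587955,596.2857804223511,1,rr,1
1.7433479135450303,550.8765858600726,1,rr,1
4.380319169965535,347.39118562501415,1,Rr,1
3.4733714058627645,35.67731707959487,1,rr,1
3.489106011021932,203.2159546218432,1,rr,1
4.441658421262308,524.6376567296112,1,Rr,1
4.896515420814517,629.2396667789917,1,Rr,1
2.9253444733731997,416.80800743670176,1,rr,1
5.156459928641315,497.30874124071767,1,Rr,1
4.1414411989310915,1147.0668112249787,1,Rr,1
4.806450218315501,721.8985563543258,1,Rr,1
4.254790054479368,275.7657734921043,1,Rr,1
4.138525293378814,658.2914377495995,1,rr,1
6.5811250690923915,72.57878950067705,0,RR,1
3.892727983894489,344.8307486337636,1,rr,1
6.260168936452528,403.0517312187991,1,Rr,1
4.233653211529735,394.61020368538703,1,Rr,1
4.18196278507746,1598.0346982689182,1,Rr,1
4.135673417454587,245.43416772025222,1,rr,1
4.219504410349554,176.72871522106473,1,rr,1
2.164189392914545,465.8741660840424,1,rr,1
5.475283647471394,748.1577104412931,1,rr,1
2.904385699117296,151.4349419971075,1,Rr,1
3.4674716203934075,249.85687787124394,0,Rr,1
3.4021696665313144,1109.8859403298459,1,rr,1
2.9499834886162413,341.1417732999333,1,rr,1
3.9884415906026467,1020.0187190391441,1,RR,1
3.9250530365532743,135.13004387869222,1,rr,1
4.17387680719609,3.377347908429041,0,rr,1
3.065728737026414,199.8026028751285,1,rr,1
4.431965786484337,98.96644178990312,0,Rr,1
4.645474272023307,174.03822288110425,1,rr,1
3.655696770349237,253.65624227517947,1,rr,1
2.512987116763861,36.025704329936914,1,rr,1
6.339563066182028,54.99285339846765,0,Rr,1
3.377695473545163,723.8100219118014,1,rr,1
4.676557562548276,241.1958240154142,0,Rr,1
2.83981686724067,70.43539927897079,1,Rr,1
3.4440801093925946,628.835404460548,1,rr,1
4.383966091682873,1.3705511628353308,0,Rr,1
4.047253093821511,9.0890175600997,0,Rr,1
3.53402271043835,498.77730524239405,1,rr,1
4.983273608794498,31.003113858954894,0,Rr,1
3.457034060591076,521.975491834317,1,rr,1
3.1424190177165556,448.58503498913853,1,Rr,1
3.5147702485428556,4.1304409566474325,0,rr,1
4.8472740960611,1.3737433092595557,0,Rr,1
3.1830123728319166,245.1772471082583,1,rr,1
3.762798047729294,1407.3185213289096,1,Rr,1
3.513921448840579,497.954335286738,1,rr,1
1.970787417527542,2.0482849422356293,0,rr,1
3.943328392550757,180.35501338606338,1,rr,1
4.918314641442525,35.113917932100044,0,Rr,1
2.3459502774282104,610.9802053781376,1,Rr,1
2.5289014552049025,733.1504022105335,1,Rr,1
3.371483461871615,187.32125574425964,0,RR,1
2.1531192756941744,451.319598182029,1,rr,1
2.715076074174319,148.66301997651846,1,rr,1
2.9771032222325866,128.4816466678261,1,RR,1
1.5432611599011907,206.47112754419757,1,rr,1
2.942813003212656,448.7802271583136,1,Rr,1
1.784495525425352,89.50772657471848,1,rr,1
5.347629147770619,2969.6704983019968,1,Rr,1
4.699971938749258,464.0665924349966,1,rr,1
3.537946534366751,4.02791560749602,0,rr,1
3.8689726298115494,301.65366743947163,1,RR,1
3.0762854652989287,1287.5440851546716,1,rr,1
3.1425112989973885,2.696265189605384,0,Rr,1
3.2568136105932473,2.0772994689895854,0,rr,1
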