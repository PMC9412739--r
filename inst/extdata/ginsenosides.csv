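no,name,rt,measured_mz,formula,fragments,class,hexose,deoxyhexose,pentose,hexuronic_acid,malonyl,dehydration,source
1,Re3,2.42,1007.54361,C48H82O19,799.48225;637.42937;475.37986,PPT,3,0,0,0,0,0,table1
2,20-O-Glc-Rf,5.65,1007.54330,C48H82O19,961.50742;799.48145;637.41575;475.37235,PPT,3,0,0,0,0,0,table1
3,20(S)-Rf2,8.56,801.49990,C42H74O14,637.40578;475.37805,PPT,1,1,0,0,0,-1,table1
4,Rf,18.60,845.49041,C42H72O14,799.48234;637.43059;475.38017,PPT,2,0,0,0,0,0,table1
5,20(S)Rh1,20.93,683.43731,C36H62O9,475.37545,PPT,1,0,0,0,0,0,table1
6,20(S)Rg2,21.04,829.49711,C42H72O13,637.42923;475.37849,PPT,1,1,0,0,0,0,table1
7,Rb1,23.00,1153.60014,C54H92O23,1107.59561;945.53787;783.43742;621.37551;459.36520,PPD,4,0,0,0,0,0,table1
8,Rb3,26.00,1123.59127,C53H90O22,1077.58161;945.54087;783.43512;621.36482;459.37230,PPD,3,0,1,0,0,0,table1
9,Rd,27.28,991.54863,C48H82O18,783.4174;621.3566;459.3527,PPD,3,0,0,0,0,0,table1
10,Gypenoside XVII,28.47,991.54833,C48H82O18,945.54101;783.48823;621.43679;459.38535,PPD,3,0,0,0,0,0,table1
11,F4,31.29,811.48546,C42H70O12,545.03567;432.87053;304.84772,PPT,1,1,0,0,0,1,table1
12,Rh4,31.99,665.42758,C36H60O8,545.05137;432.90012;304.87872,PPT,1,0,0,0,0,1,table1
13,F2,32.18,829.49573,C42H72O13,621.42669;459.3094,PPD,2,0,0,0,0,0,table1
14,Rg8,33.31,827.48143,C42H70O13,637.43765;475.35224,PPT,2,0,0,0,0,1,table1
15,Gypenoside LXXV,33.91,829.49573,C42H72O13,783.48256;621.43811;459.47407,PPD,2,0,0,0,0,0,table1
16,Rg3,34.19,829.49681,C42H72O13,783.47536;621.44161;459.47730,PPD,2,0,0,0,0,0,table1
17,Rk1,36.56,811.48512,C42H70O12,637.42498;475.38021,PPD,2,0,0,0,0,1,table1
18,Rg5,36.79,811.48530,C42H70O12,765.46792;649.93580;545.04775;432.89124;304.90873,PPD,2,0,0,0,0,1,table1
19,Rh2,37.19,667.44291,C36H62O8,631.38365;455.53292;304.91538,PPD,1,0,0,0,0,0,table1
20,CK,37.34,667.44303,C36H62O8,621.41453;459.38370,PPD,1,0,0,0,0,0,table1
21,PPT,41.17,521.38212,C30H52O4,475.38231,PPT,0,0,0,0,0,0,table1
NA,PPD,NA,NA,C30H52O3,,PPD,0,0,0,0,0,0,text
NA,Oleanolic acid,NA,NA,C30H48O3,,OLE,0,0,0,0,0,0,text
NA,Ro,NA,NA,C48H76O19,,OLE,2,0,0,1,0,0,text
NA,Re,NA,NA,C48H82O18,,PPT,2,1,0,0,0,0,text
NA,Rg1,NA,NA,C42H72O14,,PPT,2,0,0,0,0,0,text
NA,Rc,NA,NA,C53H90O22,,PPD,3,0,1,0,0,0,text
NA,Rb2,NA,NA,C53H90O22,,PPD,3,0,1,0,0,0,text
NA,Ra1,NA,NA,C58H98O26,,PPD,3,0,2,0,0,0,text
NA,F1,NA,NA,C36H62O9,,PPT,1,0,0,0,0,0,text
NA,Rk3,NA,NA,C36H60O8,,PPT,1,0,0,0,0,1,text
NA,Rh3,NA,NA,C36H60O7,,PPD,1,0,0,0,0,1,text
NA,mRb1,NA,NA,C57H94O26,,PPD,4,0,0,0,1,0,text
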