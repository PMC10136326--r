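patient_id,n_seizures,seizure_types,localization,lateralization,ictal_tachycardia
1,6,FIA,Temp,R:1|bi:5,yes
2,9,FIA,Fronto-temp,R,yes
3,2,FIA,Temp,R,yes
4,8,FIA,Temp,R,yes
5,3,FIA,Temp,L,no
6,2,FIA,Temp,L,yes
7,17,NC,NC,NC,yes
8,2,FIA,Temp,R,intermediate
9,2,FA,NC,NC,no
10,2,FIA,Fronto-par,R:1|bi:1,yes
11,5,FIA,Temp,L,intermediate
12,6,FIA,Temp,L,intermediate
13,5,FIA,Temp:3|NC:2,R:3|NC:2,intermediate
14,2,FIA,Temp,L,yes
15,2,FA:1|FIA:1,Temp:1|NC:1,R:1|NC:1,no
16,2,FA,Temp:1|NC:1,R:1|NC:1,yes
17,3,NC,NC,NC,intermediate
18,6,FA,NC,NC,no
19,3,FIA,Temp,L,yes
20,5,FIA,Temp,L:3|R:2,intermediate
21,15,FIA,Front,NC,yes
22,3,FIA,Temp,R,intermediate
23,7,FIA,Temp,L,no
24,5,FIA,Temp,L,yes
25,4,FIA,Temp,L,yes
26,22,FA:14|FIA:8,Temp:12|Fronto-temp:10,L:3|R:19,intermediate
27,9,FIA,Temp,L:4|R:3|bi:2,no
28,3,FA:2|F-BTC:1,Temp:1|Par:2,R,yes
29,2,FIA,Temp,R,yes
30,3,FIA,Fronto-temp,L,yes
31,2,FIA,Occipito-temp,L,intermediate
32,6,FIA,Temp,R,intermediate
33,8,FIA,Temp:1|Occipito-temp:7,R,yes
34,5,FIA,Fronto-temp,L,intermediate
35,5,FIA,Temp,L,yes
36,6,FIA,Temp,R,yes
37,5,FIA,Temp,R,yes
38,2,FIA,Temp,L,intermediate
39,2,FIA,Temp,bi,intermediate
40,5,FIA,Temp,R,yes
41,2,FIA,Temp,L,yes
42,8,FIA,Temp,L:3|R:1|bi:4,yes
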