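order,name,x_mm,y_mm,z_mm,lobe
1,Frontal Inf Orb L,-37,31,-12,Frontal
2,Frontal Inf Orb R,40,32,-12,Frontal
3,Frontal Inf Oper L,-49,13,19,Frontal
4,Frontal Inf Oper R,49,15,21,Frontal
5,Rectus L,-6,37,-18,Frontal
6,Rectus R,7,36,-18,Frontal
7,Frontal Inf Tri L,-47,30,14,Frontal
8,Frontal Inf Tri R,49,30,30,Frontal
9,Frontal Mid L,-34,33,35,Frontal
10,Frontal Mid R,37,33,34,Frontal
11,Frontal Mid Orb L,-32,50,-10,Frontal
12,Frontal Mid Orb R,32,53,-11,Frontal
13,Frontal Med Orb L,-6,54,-7,Frontal
14,Frontal Med Orb R,7,52,-7,Frontal
15,Frontal Sup Orb L,-18,47,-13,Frontal
16,Frontal Sup Orb R,17,48,12,Frontal
17,Frontal Sup Medial L,-6,49,31,Frontal
18,Frontal Sup Medial R,-8,51,30,Frontal
19,Frontal Sup L,-19,35,42,Frontal
20,Frontal Sup R,20,35,44,Frontal
21,Supp Motor Area L,-6,5,61,Frontal
22,Supp Motor Area R,8,0,62,Frontal
23,Precentral L,-40,-6,51,Frontal
24,Precentral R,40,-8,52,Frontal
25,Rolandic Oper L,-48,-8,14,Frontal
26,Rolandic Oper R,52,-6,15,Frontal
27,Insula L,-36,7,3,Frontal
28,Insula R,38,6,2,Frontal
29,Temporal Pole Mid L,-37,15,-34,Temporal
30,Temporal Pole Mid R,43,15,-12,Temporal
31,Temporal Pole Sup L,-41,15,-34,Temporal
32,Temporal Pole Sup R,47,15,-32,Temporal
33,Temporal Sup L,-54,-21,7,Temporal
34,Temporal Sup R,57,-22,7,Temporal
35,Temporal Mid L,-57,-34,-2,Temporal
36,Temporal Mid R,56,-37,-1,Temporal
37,Temporal Inf L,-51,-28,-23,Temporal
38,Temporal Inf R,53,-31,-22,Temporal
39,Heschl L,-42,-19,10,Temporal
40,Heschl R,46,-17,10,Temporal
41,Olfactory L,-9,15,-12,Limbic
42,Olfactory R,8,16,-11,Limbic
43,Cingulum Ant L,-5,35,14,Limbic
44,Cingulum Ant R,7,37,16,Limbic
45,Cingulum Mid L,-6,-15,42,Limbic
46,Cingulum Mid R,7,-9,40,Limbic
47,Cingulum Post L,-6,-43,25,Limbic
48,Cingulum Post R,6,-42,22,Limbic
49,Hippocampus L,-26,-21,-10,Limbic
50,Hippocampus R,28,-20,-10,Limbic
51,ParaHippocampus L,-22,-16,-21,Limbic
52,ParaHippocampus R,24,-15,-20,Limbic
53,Amygdala L,-24,-1,-17,Limbic
54,Amygdala R,26,1,-18,Limbic
55,Caudate L,-12,11,9,Limbic
56,Caudate R,14,12,9,Limbic
57,Putamen L,-25,4,2,Limbic
58,Putamen R,27,5,2,Limbic
59,Pallidum L,-19,0,0,Limbic
60,Pallidum R,20,0,0,Limbic
61,Thalamus L,-12,-18,8,Limbic
62,Thalamus R,12,-18,8,Limbic
63,Paracentral Lobule L,-9,-25,70,Parietal
64,Paracentral Lobule R,6,-32,68,Parietal
65,Postcentral L,-43,-23,49,Parietal
66,Postcentral R,40,-25,53,Parietal
67,Parietal Sup L,-24,-60,59,Parietal
68,Parietal Sup R,25,-59,62,Parietal
69,Parietal Inf L,-44,-46,47,Parietal
70,Parietal Inf R,45,-46,50,Parietal
71,SupraMarginal L,-57,-34,30,Parietal
72,SupraMarginal R,5,-32,34,Parietal
73,Angular L,-45,-61,36,Parietal
74,Angular R,45,-60,39,Parietal
75,Precuneus L,-8,-56,48,Parietal
76,Precuneus R,9,-56,44,Parietal
77,Cuneus L,-7,-80,27,Occipital
78,Cuneus R,13,79,28,Occipital
79,Lingual L,-16,-68,-5,Occipital
80,Lingual R,15,-67,-4,Occipital
81,Fusiform L,-32,-40,-20,Occipital
82,Fusiform R,33,-39,-20,Occipital
83,Calcarine L,-8,-79,6,Occipital
84,Calcarine R,15,-73,9,Occipital
85,Occipital Sup L,-18,-84,28,Occipital
86,Occipital Sup R,23,-81,31,Occipital
87,Occipital Mid L,-33,-81,16,Occipital
88,Occipital Mid R,36,-80,19,Occipital
89,Occipital Inf L,-37,-78,-8,Occipital
90,Occipital Inf R,37,-82,-8,Occipital
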