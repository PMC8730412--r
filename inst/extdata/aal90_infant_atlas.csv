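"index","name","hemisphere"
0,"precentral gyrus, left","left"
1,"precentral gyrus, right","right"
2,"superior frontal gyrus (dorsal), left","left"
3,"superior frontal gyrus (dorsal), right","right"
4,"superior orbitofrontal cortex, left","left"
5,"superior orbitofrontal cortex, right","right"
6,"middle frontal gyrus, left","left"
7,"middle frontal gyrus, right","right"
8,"middle orbitofrontal cortex, left","left"
9,"middle orbitofrontal cortex, right","right"
10,"opercular inferior frontal gyrus, left","left"
11,"opercular inferior frontal gyrus, right","right"
12,"triangular inferior frontal gyrus, left","left"
13,"triangular inferior frontal gyrus, right","right"
14,"inferior orbitofrontal cortex, left","left"
15,"inferior orbitofrontal cortex, right","right"
16,"rolandic operculum, left","left"
17,"rolandic operculum, right","right"
18,"supplementary motor area, left","left"
19,"supplementary motor area, right","right"
20,"olfactory cortex, left","left"
21,"olfactory cortex, right","right"
22,"superior frontal gyrus (medial), left","left"
23,"superior frontal gyrus (medial), right","right"
24,"superior frontal gyrus (medial orbital), left","left"
25,"superior frontal gyrus (medial orbital), right","right"
26,"gyrus rectus, left","left"
27,"gyrus rectus, right","right"
28,"insula, left","left"
29,"insula, right","right"
30,"anterior cingulate gyrus, left","left"
31,"anterior cingulate gyrus, right","right"
32,"middle cingulate gyrus, left","left"
33,"middle cingulate gyrus, right","right"
34,"posterior cingulate gyrus, left","left"
35,"posterior cingulate gyrus, right","right"
36,"hippocampus, left","left"
37,"hippocampus, right","right"
38,"parahippocampal gyrus, left","left"
39,"parahippocampal gyrus, right","right"
40,"amygdala, left","left"
41,"amygdala, right","right"
42,"calcarine cortex, left","left"
43,"calcarine cortex, right","right"
44,"cuneus, left","left"
45,"cuneus, right","right"
46,"lingual gyrus, left","left"
47,"lingual gyrus, right","right"
48,"superior occipital gyrus, left","left"
49,"superior occipital gyrus, right","right"
50,"middle occipital gyrus, left","left"
51,"middle occipital gyrus, right","right"
52,"inferior occipital gyrus, left","left"
53,"inferior occipital gyrus, right","right"
54,"fusiform gyrus, left","left"
55,"fusiform gyrus, right","right"
56,"postcentral gyrus, left","left"
57,"postcentral gyrus, right","right"
58,"superior parietal gyrus, left","left"
59,"superior parietal gyrus, right","right"
60,"inferior parietal lobule, left","left"
61,"inferior parietal lobule, right","right"
62,"supramarginal gyrus, left","left"
63,"supramarginal gyrus, right","right"
64,"angular gyrus, left","left"
65,"angular gyrus, right","right"
66,"precuneus, left","left"
67,"precuneus, right","right"
68,"paracentral lobule, left","left"
69,"paracentral lobule, right","right"
70,"caudate nucleus, left","left"
71,"caudate nucleus, right","right"
72,"putamen, left","left"
73,"putamen, right","right"
74,"globus pallidus, left","left"
75,"globus pallidus, right","right"
76,"thalamus, left","left"
77,"thalamus, right","right"
78,"heschl gyrus, left","left"
79,"heschl gyrus, right","right"
80,"superior temporal gyrus, left","left"
81,"superior temporal gyrus, right","right"
82,"superior temporal pole, left","left"
83,"superior temporal pole, right","right"
84,"middle temporal gyrus, left","left"
85,"middle temporal gyrus, right","right"
86,"middle temporal pole, left","left"
87,"middle temporal pole, right","right"
88,"inferior temporal gyrus, left","left"
89,"inferior temporal gyrus, right","right"
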