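scenario_id,target1,target2,target3,appropriateness_mean,appropriateness_sd,relevance_mean,relevance_sd,suitability_mean,suitability_sd
1,Red meat,Oily fish,Fruit,4.0,1.2,4.0,1.2,4.0,1.2
2,Legume,Salt,Healthy fat,3.5,1.1,3.5,1.1,3.3,1.1
3,Alcohol,Red meat,Oily fish,4.8,0.4,4.0,1.0,4.0,1.0
4,Red meat,Fruit,Legume,3.8,0.4,4.3,0.4,3.5,0.5
5,Red meat,Legume,Whole grain,4.3,0.4,3.8,0.8,4.0,0.7
6,Dairy,Whole grain,Oily fish,3.3,0.8,2.8,1.1,2.8,1.1
7,Whole grain,Red meat,Oily fish,3.8,0.4,3.5,0.9,4.0,1.2
8,Legume,Red meat,Whole grain,3.0,1.2,3.0,1.2,3.0,1.2
9,Whole grain,Legume,Sugar,3.3,0.4,2.8,1.1,3.3,0.4
10,Legume,Sugar,Healthy fats,4.0,0.7,4.0,0.7,3.8,1.3
11,Sugar,Red meat,Legume,3.8,0.8,3.0,1.4,3.0,1.4
12,Healthy fat,Fruit,Dairy,3.3,1.3,3.3,0.8,3.0,1.0
13,Alcohol,Whole grain,Legume,3.5,0.5,3.5,1.1,3.3,0.8
14,Whole grain,Healthy fat,Sugar,3.5,0.9,3.0,0.7,3.5,0.9
15,Whole grain,Legume,Oily fish,2.5,1.5,2.5,1.5,2.5,1.5
16,Legume,Healthy fat,Sugar,2.5,0.5,2.5,0.5,2.5,0.5
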