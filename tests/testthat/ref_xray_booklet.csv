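element,quantity,value
Mo,ka1_kev,17.479
Mo,ka2_kev,17.374
Mo,kb1_kev,19.608
Mo,k_edge_kev,20.000
Mo,fluor_yield,0.765
Cd,ka1_kev,23.174
Cd,ka2_kev,22.984
Cd,kb1_kev,26.096
Cd,k_edge_kev,26.711
Cd,fluor_yield,0.843
Te,ka1_kev,27.472
Te,ka2_kev,27.202
Te,kb1_kev,30.995
Te,k_edge_kev,31.814
Te,fluor_yield,0.875
La,ka1_kev,33.442
La,ka2_kev,33.034
La,kb1_kev,37.801
La,k_edge_kev,38.925
La,fluor_yield,0.906
Gd,ka1_kev,42.996
Gd,ka2_kev,42.309
Gd,kb1_kev,48.697
Gd,k_edge_kev,50.239
Gd,fluor_yield,0.932
W,ka1_kev,59.318
W,ka2_kev,57.982
W,kb1_kev,67.244
W,k_edge_kev,69.525
W,fluor_yield,0.958
Pt,ka1_kev,66.832
Pt,ka2_kev,65.112
Pt,kb1_kev,75.748
Pt,k_edge_kev,78.395
Pt,fluor_yield,0.963
Au,ka1_kev,68.804
Au,ka2_kev,66.990
Au,kb1_kev,77.985
Au,k_edge_kev,80.725
Au,fluor_yield,0.964
Pb,ka1_kev,74.969
Pb,ka2_kev,72.804
Pb,kb1_kev,84.936
Pb,k_edge_kev,88.005
Pb,fluor_yield,0.967
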