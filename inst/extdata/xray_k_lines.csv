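element,line,energy_kev,rel_intensity
Mo,Ka1,17.479,100
Mo,Ka2,17.374,52.5
Mo,Kb1,19.608,29.7375
Cd,Ka1,23.174,100
Cd,Ka2,22.984,53.1
Cd,Kb1,26.096,31.3855
Te,Ka1,27.472,100
Te,Ka2,27.202,53.8
Te,Kb1,30.995,33.067
La,Ka1,33.442,100
La,Ka2,33.034,54.3
La,Kb1,37.801,34.7175
Gd,Ka1,42.996,100
Gd,Ka2,42.309,54.8
Gd,Kb1,48.697,36.378
W,Ka1,59.318,100
W,Ka2,57.982,57.7
W,Kb1,67.244,40.2135
Pt,Ka1,66.832,100
Pt,Ka2,65.112,58.8
Pt,Kb1,75.748,41.6056
Au,Ka1,68.804,100
Au,Ka2,66.99,59
Au,Kb1,77.985,41.976
Pb,Ka1,74.969,100
Pb,Ka2,72.804,59.4
Pb,Kb1,84.936,42.7192
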