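element,z,a,k_edge,fluor_yield,jump
H,1,1.008,0.0136,0,12
Be,4,9.0122,0.1115,0.00045,12
C,6,12.011,0.2842,0.0028,12
O,8,15.999,0.5431,0.0083,12
F,9,18.998,0.6971,0.013,12
Mo,42,95.95,20,0.765,6.995
Cd,48,112.414,26.711,0.843,6.68
Te,52,127.6,31.814,0.875,6.47
La,57,138.905,38.925,0.906,6.2075
Gd,64,157.25,50.2391,0.932,5.84
W,74,183.84,69.525,0.958,5.315
Pt,78,195.084,78.395,0.963,5.105
Au,79,196.967,80.725,0.964,5.0525
Pb,82,207.2,88.005,0.967,4.895
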