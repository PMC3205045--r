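element,monoisotopic,average
H,1.00782503207,1.008
Li,7.01600455,6.94
Be,9.0121822,9.0122
B,11.0093054,10.81
C,12.0,12.011
N,14.0030740048,14.007
O,15.9949146196,15.999
F,18.99840322,18.998
Na,22.9897692809,22.990
Mg,23.9850417,24.305
Al,26.98153863,26.982
Si,27.9769265325,28.085
P,30.97376163,30.974
S,31.972071,32.06
Cl,34.96885268,35.45
K,38.96370668,39.098
Ca,39.96259098,40.078
Ti,47.9479463,47.867
Cr,51.9405075,51.996
Mn,54.9380451,54.938
Fe,55.9349375,55.845
Co,58.933195,58.933
Ni,57.9353429,58.693
Cu,62.9295975,63.546
Zn,63.9291422,65.38
As,74.9215965,74.922
Se,79.9165213,78.971
Br,78.9183371,79.904
Mo,97.9054082,95.95
Ru,101.9043493,101.07
Rh,102.905504,102.906
Pd,105.903486,106.42
Ag,106.905097,107.868
Sn,119.9021947,118.71
Sb,120.9038157,121.76
I,126.904473,126.904
Ba,137.9052472,137.327
Pt,194.9647911,195.084
Au,196.9665687,196.967
Hg,201.970643,200.592
Pb,207.9766521,207.2
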