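metal,layer,factor1,factor2
Cu,surface,35.60,18.80
Zn,surface,58.20,74.20
Ni,surface,22.50,21.40
Pb,surface,9.62,40.90
Cr,surface,47.90,38.60
Cd,surface,0.41,0.04
As,surface,5.64,23.10
Hg,surface,0.09,0.04
Cu,deep,23.128,19.216
Zn,deep,34.885,76.701
Ni,deep,15.193,21.952
Pb,deep,6.119,36.726
Cr,deep,32.276,40.958
Cd,deep,0.183,0.158
As,deep,8.796,13.827
Hg,deep,0.05,0.039
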