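metal,layer,min,max,mean,cv
Cu,surface,25.90,68.90,54.34,0.13
Zn,surface,99.00,169.00,132.72,0.09
Ni,surface,23.60,50.00,43.76,0.10
Pb,surface,27.50,71.80,50.43,0.14
Cr,surface,50.00,97.00,86.56,0.09
Cd,surface,0.17,1.01,0.46,0.32
As,surface,16.90,41.50,28.99,0.17
Hg,surface,0.05,0.23,0.14,0.21
Cu,deep,12.00,66.20,42.76,0.31
Zn,deep,54.00,200.00,111.61,0.21
Ni,deep,16.80,48.40,37.26,0.24
Pb,deep,23.20,82.50,42.94,0.23
Cr,deep,31.00,100.00,73.26,0.24
Cd,deep,0.11,1.62,0.36,0.49
As,deep,5.40,47.60,24.27,0.31
Hg,deep,0.02,0.21,0.09,0.37
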