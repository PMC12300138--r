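crop_type,Cu,Zn,Ni,Pb,Cr,Cd,As,Hg
leafy,0.10,0.25,0.040,0.020,0.020,0.30,0.030,0.015
fruit,0.05,0.10,0.020,0.008,0.008,0.10,0.010,0.008
root,0.08,0.20,0.030,0.015,0.015,0.25,0.020,0.010
inflorescence,0.12,0.30,0.050,0.025,0.025,0.35,0.040,0.020
sugarcane,0.09,0.22,0.045,0.020,0.020,0.20,0.035,0.018
banana,0.11,0.28,0.050,0.022,0.022,0.30,0.040,0.020
none,0,0,0,0,0,0,0,0
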