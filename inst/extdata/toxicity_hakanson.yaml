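# Hakanson toxic-response coefficients (dimensionless).
tr:
  Cu: 5
  Zn: 1
  Ni: 5
  Pb: 5
  Cr: 2
  Cd: 30
  As: 10
  Hg: 40
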