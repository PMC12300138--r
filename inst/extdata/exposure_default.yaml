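# Exposure parameters for the dose model, per population.
# Each entry is either {value: x} (point) or a distribution:
#   {normal: {mean, sd}}  or  {triangular: {min, mode, max}}
# Units: IngR mg/day; InhR m3/day; SA cm2; AF mg/cm2/day; ABS -;
# EF days/year; ED years; BW kg; AT_nc, AT_ca days; PEF m3/kg;
# CF kg/mg; IR_food kg/day (fresh weight).
child:
  IngR: {triangular: {min: 100, mode: 200, max: 250}}
  InhR: {value: 7.6}
  SA: {value: 2800}
  AF: {value: 0.2}
  ABS: {value: 0.001}
  EF: {triangular: {min: 180, mode: 350, max: 365}}
  ED: {value: 6}
  BW: {normal: {mean: 15, sd: 2.5}}
  AT_nc: {value: 2190}
  AT_ca: {value: 25550}
  PEF: {value: 1.36e+09}
  CF: {value: 1.0e-06}
  IR_food: {normal: {mean: 0.232, sd: 0.046}}
adult:
  IngR: {triangular: {min: 50, mode: 100, max: 150}}
  InhR: {value: 14.5}
  SA: {value: 5700}
  AF: {value: 0.07}
  ABS: {value: 0.001}
  EF: {triangular: {min: 180, mode: 350, max: 365}}
  ED: {value: 24}
  BW: {normal: {mean: 60, sd: 8}}
  AT_nc: {value: 8760}
  AT_ca: {value: 25550}
  PEF: {value: 1.36e+09}
  CF: {value: 1.0e-06}
  IR_food: {normal: {mean: 0.345, sd: 0.069}}
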