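stem:
  kind: isotropic
  E: 1.15e+11
  nu: 0.30
  name: stem (TiAl6V4)
stem_flexible:
  kind: isotropic
  E: 2.0e+10
  nu: 0.30
  name: stem (porous Ta)
stem_stiff:
  kind: isotropic
  E: 2.1e+11
  nu: 0.30
  name: stem (CoCr)
cement:
  kind: isotropic
  E: 2.0e+9
  nu: 0.40
  name: PMMA
bone:
  kind: orthotropic
  EX: 1.2e+10
  EY: 2.0e+10
  EZ: 1.34e+10
  nuXY: 0.22
  nuYZ: 0.35
  nuXZ: 0.38
  GXY: 5.61e+9
  GYZ: 6.23e+9
  GXZ: 4.53e+9
  frame: cylindrical
  density: 1.8
  name: cortical bone
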