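name: nim_petct
units:
  length: mm
  activity: kBq/mL
body:
  half_width: 150.0
  half_height: 115.0
  corner_radius: 77.0
  length: 180.0
spheres:
- diameter: 4.0
  x: -14.804449379864193
  'y': 55.250957263734712
  z: 0.0
  role: hot
- diameter: 7.0
  x: -49.536653096469898
  'y': 28.599999999999998
  z: 0.0
  role: hot
- diameter: 10.0
  x: -55.250957263734719
  'y': -14.804449379864177
  z: 0.0
  role: hot
- diameter: 13.0
  x: -28.600000000000026
  'y': -49.536653096469884
  z: 0.0
  role: hot
- diameter: 17.0
  x: 14.804449379864161
  'y': -55.250957263734712
  z: 0.0
  role: hot
- diameter: 22.0
  x: 49.536653096469877
  'y': -28.600000000000009
  z: 0.0
  role: hot
- diameter: 28.0
  x: 55.250957263734712
  'y': 14.804449379864186
  z: 0.0
  role: cold
- diameter: 37.0
  x: 28.600000000000009
  'y': 49.536653096469891
  z: 0.0
  role: cold
lung:
  diameter: 50.0
  density: 0.3
ct_module:
  diameter: 150.0
  thickness: 20.0
  center_z: 100.0
  water_boundary_radius: 58.0
  inserts:
  - contrast_pct: 0.5
    hu_delta: 5.0
    diameter: 20.0
    x: 0.0
    'y': 40.0
  - contrast_pct: 1.0
    hu_delta: 10.0
    diameter: 20.0
    x: -34.641016151377542
    'y': -20.000000000000014
  - contrast_pct: 1.5
    hu_delta: 15.0
    diameter: 20.0
    x: 34.641016151377535
    'y': -20.000000000000004
background_activity: 6.6
hot_activity: 26.399999999999999
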