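name: nema_iec
units:
  length: mm
  activity: kBq/mL
body:
  half_width: 150.0
  half_height: 115.0
  corner_radius: 77.0
  length: 180.0
spheres:
- diameter: 10.0
  x: -49.536653096469898
  'y': 28.599999999999998
  z: 0.0
  role: hot
- diameter: 13.0
  x: -49.536653096469891
  'y': -28.600000000000019
  z: 0.0
  role: hot
- diameter: 17.0
  x: 0.0
  'y': -57.200000000000003
  z: 0.0
  role: hot
- diameter: 22.0
  x: 49.536653096469877
  'y': -28.600000000000009
  z: 0.0
  role: hot
- diameter: 28.0
  x: 49.536653096469898
  'y': 28.599999999999998
  z: 0.0
  role: cold
- diameter: 37.0
  x: 0.0
  'y': 57.200000000000003
  z: 0.0
  role: cold
lung:
  diameter: 50.0
  density: 0.3
ct_module: ~
background_activity: 6.6
hot_activity: 26.399999999999999
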