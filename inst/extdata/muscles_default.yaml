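Tmax:
  se: 120.0
  sf: 340.0
  ee: 160.0
  ef: 160.0
fl_center:
  se: 1.2
  sf: 2.25
  ee: 1.3
  ef: 0.8
fl_width:
- 0.5
vmax:
- 12.0
fv_curvature:
- 4.0
fv_ecc:
- 1.15
shoulder_limits:
- -1.0
- 2.4
elbow_limits:
- 0.0
- 2.6
passive_scale:
- 2.0
passive_decay:
- 0.05
passive_damping:
- 0.3
Ta:
- 0.02
Td:
- 0.04
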