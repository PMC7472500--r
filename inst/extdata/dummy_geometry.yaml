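# Synthetic dummy-foot rig geometry (units: mm, right foot).
#
# Lab frame: X anterior (toe direction), Y superior, Z right-lateral.
# Three rigid styrene-foam box segments rest on reference plates A (toe),
# B (forefoot), C (rearfoot). Box outer dimensions follow the physical rig
# (toe 30 x 80 x 55 mm H x W x L, forefoot 50 x 80 x 95, rearfoot
# 50 x 65 x 75); the per-landmark coordinates are NOMINAL, synthetic
# placements on plausible box faces -- the physical rig's exact marker
# positions were never published. Landmarks shared between adjoining
# segments (H1 H2 H5 B5 NV) are attached once per segment (duplicates),
# giving 12 unique + 5 duplicated = 17 physical markers.
units: mm
boxes:
  toe:      {x_min: 170, x_max: 225, y_min: 0, y_max: 30, z_min: -40.0, z_max: 40.0}
  forefoot: {x_min:  75, x_max: 170, y_min: 0, y_max: 50, z_min: -40.0, z_max: 40.0}
  rearfoot: {x_min:   0, x_max:  75, y_min: 0, y_max: 50, z_min: -32.5, z_max: 32.5}
markers:
  - {name: P1, box: toe,      pos: [220, 30, -25]}
  - {name: H1, box: toe,      pos: [174, 30, -25]}
  - {name: H2, box: toe,      pos: [174, 30, 0]}
  - {name: H5, box: toe,      pos: [174, 30, 25]}
  - {name: H1, box: forefoot, pos: [166, 50, -25]}
  - {name: H2, box: forefoot, pos: [166, 50, 0]}
  - {name: H5, box: forefoot, pos: [166, 50, 25]}
  - {name: B1, box: forefoot, pos: [78, 50, -28]}
  - {name: B2, box: forefoot, pos: [82, 50, -5]}
  - {name: B5, box: forefoot, pos: [78, 50, 30]}
  - {name: NV, box: forefoot, pos: [78, 50, -30]}
  - {name: NV, box: rearfoot, pos: [72, 45, -30]}
  - {name: B5, box: rearfoot, pos: [72, 45, 30]}
  - {name: ST, box: rearfoot, pos: [60, 25, -32.5]}
  - {name: PT, box: rearfoot, pos: [55, 20, 32.5]}
  - {name: C1, box: rearfoot, pos: [5, 45, 0]}
  - {name: C2, box: rearfoot, pos: [2, 8, 0]}
plates:
  A: {box: toe,      o: [175, -20, -45], x: [225, -20, -45], z: [175, -20, 45]}
  B: {box: forefoot, o: [80, -20, -45],  x: [165, -20, -45], z: [80, -20, 45]}
  C: {box: rearfoot, o: [5, -20, -40],   x: [70, -20, -40],  z: [5, -20, 40]}
# rotation pivots of the two moving ends (toe/forefoot and forefoot/rearfoot
# joint lines at the plate surface)
pivots:
  toe:      [170, 0, 0]
  rearfoot: [75, 0, 0]
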