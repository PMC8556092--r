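# Example item-by-item WET chains for the 330 MeV/u, 10x10 cm^2 setup.
# The chain totals reproduce the published water-equivalent peak depths
# (174.9 mm + 20.882 mm = 195.782 mm for the plane-parallel in-field
# chamber; 164.65 mm + 33.41 mm = 198.06 mm for the Farmer chamber), but
# the per-item decomposition is illustrative: the source material does not
# enumerate the individual contributions.
radius: 3.05
reference:
  chain:
    - {label: "Bragg peak reference chamber 34080", wet_mm: 2.0648}
    - {label: "water tank wall (6.72 mm PMMA)", physical_mm: 6.72, wet_mm: 7.7952}
    - {label: "anticollision clearance (7 mm water)", physical_mm: 7.0, wet_mm: 7.0}
    - {label: "in-field chamber 34070 window", physical_mm: 3.47, wet_mm: 4.022}
test:
  chain:
    - {label: "Bragg peak reference chamber 34080", wet_mm: 2.0648}
    - {label: "water tank wall (6.72 mm PMMA)", physical_mm: 6.72, wet_mm: 7.7952}
    - {label: "clearance to point of measurement (water)", wet_mm: 22.999}
    - {label: "Farmer 30013 wall", physical_mm: 0.425, wet_mm: 0.551}
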