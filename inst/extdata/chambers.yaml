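# Bundled ionization chamber geometry records.
# WET rules: PMMA x 1.16; graphite x density x (1.16/1.19); lacquer/water x 1.
# The 34080 record folds its 0.02 mm graphite coat into the 1.16 mm PMMA
# electrode layer, matching the published worked calculation
# (0.62 + 1.16) mm x 1.16 = 2.0648 mm.
- name: "PTW 34080"
  kind: plane_parallel
  active_volume: 10.5
  pom_convention: "inside of entrance window, center"
  pom_offset: 0
  window_layers:
    - {material: PMMA, thickness: 0.62, density: 1.19}
    - {material: PMMA, thickness: 1.16, density: 1.19}
- name: "PTW 34070"
  kind: plane_parallel
  active_volume: 10.5
  pom_convention: "inside of entrance window, center"
  pom_offset: 0
  window_layers:
    - {material: PMMA, thickness: 3.35, density: 1.19}
    - {material: graphite, thickness: 0.02, density: 1.85}
    - {material: lacquer, thickness: 0.1, density: 1.0}
- name: "PTW 30013"
  kind: cylindrical
  active_volume: 0.6
  inner_radius: 3.05
  pom_convention: "on detector axis, 13 mm behind the tip"
  pom_offset: 13
  window_layers:
    - {material: PMMA, thickness: 0.335, density: 1.19}
    - {material: graphite, thickness: 0.09, density: 1.85}
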