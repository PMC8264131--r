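# Example study configuration: the six-condition gentamicin membrane/flow
# grid (fixed observed membrane clearances per condition, ml/min).
seed: 20210624
noise:
  cv: 0.05
grid: [1, 5, 10, 15, 20, 30, 40, 60]
membranes:
  - {name: SF21E,    material: triacetate,  area: 2.1, model: fixed_clearance, cl_membrane: 131.52}
  - {name: SF17UX,   material: triacetate,  area: 1.7, model: fixed_clearance, cl_membrane: 160.75}
  - {name: SF21UX,   material: triacetate,  area: 2.1, model: fixed_clearance, cl_membrane: 178.25}
  - {name: F80s,     material: polysulfone, area: 1.8, model: fixed_clearance, cl_membrane: 137.62}
  - {name: Fx80,     material: polysulfone, area: 1.8, model: fixed_clearance, cl_membrane: 187.90}
  - {name: CAHP-170, material: diacetate,   area: 1.7, model: fixed_clearance, cl_membrane: 90.12}
drugs:
  - {name: gentamicin, c0: 10, fraction_bound: 0}
settings:
  - {name: fast, bfr: 400, dfr: 800, ufr: 0, hematocrit: 0.35, blood_volume: 2000}
conditions:
  - {membrane: SF21E,    drug: gentamicin, settings: fast, replicates: 12}
  - {membrane: SF17UX,   drug: gentamicin, settings: fast, replicates: 12}
  - {membrane: SF21UX,   drug: gentamicin, settings: fast, replicates: 17}
  - {membrane: F80s,     drug: gentamicin, settings: fast, replicates: 12}
  - {membrane: Fx80,     drug: gentamicin, settings: fast, replicates: 12}
  - {membrane: CAHP-170, drug: gentamicin, settings: fast, replicates: 12}
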