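# Depletion-scan scenario: four-component chromatin (target, two off-targets,
# inert) with an antibody 110-fold selective over off-target 1 and 22-fold
# over off-target 2, plus two small spike-in species reported separately.
# Concentrations in uM, binding constants in 1/uM.
antibody_total: 6
species:
  - {name: target,   total: 10.4, K: 11,  spike: false}
  - {name: offtgt1,  total: 0.3,  K: 0.1, spike: false}
  - {name: offtgt2,  total: 0.3,  K: 0.5, spike: false}
  - {name: spike_t,  total: 0.03, K: 11,  spike: true}
  - {name: spike_o,  total: 0.03, K: 0.5, spike: true}
scenario: case2
total_constant: 11
grid: {from: 0.5, to: 10.4, points: 34}
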