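# Four-component HIV medication-adherence case study: a 2^4 factorial ORCT
# with advantage-dependent component effects (gain = a + b * S).
design:
  components:
    - {name: A, cost_on: 100}   # Motivational Interviewing
    - {name: B, cost_on: 125}   # Peer Support
    - {name: C, cost_on: 200}   # Navigator
    - {name: D, cost_on: 250}   # Skill-Building Sessions
effects:
  main:
    A: {a: 0.5, b: 0.5}
    B: {a: 0.0, b: 1.0}
    C: {a: 0.0, b: 0.0}
    D: {a: 1.0, b: -1.0}
  interactions:
    "B:C": {a: 1.0, b: -1.0}   # Navigator offsets Peer Support's gradient
  baseline: 0.0
simulation:
  G: 5
  per_cell_n: 10
  noise_sd: 1.0
  seed: 7
model:
  terms: two-way
  backend: closed
equity:
  tolerance: 2sd
valuation:
  wtp: [170, 330, 580, 830]
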