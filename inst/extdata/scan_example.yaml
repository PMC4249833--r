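# Example grid-scan specification for a three-phenotype fit.
# Each entry is either a fixed value or [min, max, step] in 1/day.
# Growth rates are held fixed here: a fraction-only objective cannot
# identify their absolute scale (only differences matter).
growth:
  L: 0.73
  B: 0.85
  S: 0.69
transitions:
  "L->B": [0, 1, 0.05]
  "L->S": [0, 1, 0.05]
  "B->L": [0, 1, 0.05]
  "B->S": [0, 1, 0.05]
  "S->L": [0, 1, 0.05]
  "S->B": [0, 1, 0.05]
feasibility: coexistent_growth
objective: sse
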