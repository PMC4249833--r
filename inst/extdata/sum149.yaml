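# SUM149 breast-cancer cell line: luminal (L), basal (B), stem (S).
# Published growth/transition estimates read under the column convention
# recorded in table1_mapping.yaml.  Rates in 1/day.
labels: [L, B, S]
growth:
  L: 0.95
  B: 0.91
  S: 0.69
transitions:
  "L->S": 0.03
  "B->L": 0.02
  "B->S": 0.01
  "S->L": 0.30
  "S->B": 0.05
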